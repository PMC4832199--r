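## Feature stacks and the cross-validated experiment driver. RANK: ranklet
## responses -> GLCM Haralick statistics (12-feature subset) -> angle
## averaging -> bootstrap selection -> SVM. CURVE: sub-band decomposition ->
## GLCM Haralick (14) -> angle averaging -> SVM. MORPH: mask geometry ->
## SVM. SDAE: pretrained + fine-tuned network on 28x28 patches with
## auxiliary geometry inputs.

#' Prepare stored cases into classifier-ready case records
#'
#' Crops each slice around its mask with the given margin and converts it to
#' a normalized 28x28 `roi_sample`.
#'
#' @param cases List of `synth_case` objects (e.g. from [read_manifest()]).
#' @param roi_margin Fractional crop margin per side around the mask
#'   bounding box (context tissue around the lesion).
#' @return List of `case_record` objects.
#' @export
prepare_case_records <- function(cases, roi_margin = 0.25) {
  lapply(cases, function(cs) {
    slices <- lapply(seq_along(cs$images), function(j) {
      roi <- extract_roi(cs$images[[j]], cs$masks[[j]], margin = roi_margin)
      to_patch(roi, label = cs$label, case_id = cs$case_id,
               slice_index = j - 1L)
    })
    case_record(cs$case_id, cs$label, slices, thickness = cs$thickness)
  })
}

## Haralick features (possibly a subset), averaged over GLCM angles, of one
## quantized image.
glcm_angle_features <- function(qimg, spec, subset = NULL) {
  per_angle <- lapply(spec$angles, function(ang) {
    haralick(glcm(qimg, spec, spec$distances[1], ang), subset = subset)
  })
  average_over_angles(per_angle)
}

#' RANK texture features of one image
#'
#' Ranklet responses at each configured window size and orientation are
#' mapped from `[-1, 1]` to gray levels, a GLCM is computed per angle, the
#' 12-feature Haralick subset is derived and averaged over angles; features
#' are named `w<size>_<orientation>.<feature>`.
#'
#' @param img Grayscale matrix (the pre-resize ROI crop or the 28x28 patch).
#' @param rk A [ranklet_spec()].
#' @param gl A [glcm_spec()]; default 8 levels for the compact rank images.
#' @return Named numeric vector.
#' @export
rank_features <- function(img, rk = ranklet_spec(),
                          gl = glcm_spec(levels = 8L)) {
  responses <- ranklet_transform(img, rk)
  out <- lapply(names(responses), function(nm) {
    q <- quantize_gray((responses[[nm]] + 1) / 2, gl$levels)
    f <- glcm_angle_features(q, gl, subset = haralick_names_12)
    stats::setNames(f, paste0(nm, ".", names(f)))
  })
  unlist(out)
}

#' CURVE texture features of one image
#'
#' Sub-band decomposition (2-level separable wavelet by default), then per
#' band the 14 Haralick features of the GLCM averaged over angles; features
#' are named `<band>.<feature>`.
#'
#' @param img Grayscale matrix with dimensions divisible by 4.
#' @param gl A [glcm_spec()].
#' @param method Decomposition method passed to [decompose()].
#' @return Named numeric vector.
#' @export
curve_features <- function(img, gl = glcm_spec(levels = 16L),
                           method = "wavelet") {
  bands <- decompose(img, method = method)
  out <- lapply(names(bands), function(nm) {
    q <- quantize_gray(minmax01(bands[[nm]]), gl$levels)
    f <- glcm_angle_features(q, gl)
    stats::setNames(f, paste0(nm, ".", names(f)))
  })
  unlist(out)
}

#' Extract a feature table for a baseline stack
#'
#' `"rank"` and `"curve"` produce one row per slice (computed on the
#' normalized 28x28 patch); `"morph"` produces one row per case from the
#' masks. Feature extraction involves no training statistics, so tables are
#' computed once and reused across cross-validation folds.
#'
#' @param cases List of `synth_case` objects.
#' @param stack `"rank"`, `"curve"` or `"morph"`.
#' @param roi_margin Crop margin for the texture stacks.
#' @return data.frame with `case_id`, `slice_index`, `label` and feature
#'   columns.
#' @export
extract_features <- function(cases, stack = c("rank", "curve", "morph"),
                             roi_margin = 0.25) {
  stack <- match.arg(stack)
  if (stack == "morph") {
    rows <- lapply(cases, function(cs) {
      data.frame(case_id = cs$case_id, slice_index = NA_integer_,
                 label = cs$label, t(morph_features(cs)),
                 stringsAsFactors = FALSE)
    })
    return(do.call(rbind, rows))
  }
  records <- prepare_case_records(cases, roi_margin)
  fun <- if (stack == "rank") rank_features else curve_features
  rows <- lapply(records, function(cr) {
    do.call(rbind, lapply(cr$slices, function(s) {
      data.frame(case_id = s$case_id, slice_index = s$slice_index,
                 label = s$label, t(fun(s$patch)),
                 stringsAsFactors = FALSE, check.names = FALSE)
    }))
  })
  do.call(rbind, rows)
}

feature_cols <- function(tab) setdiff(names(tab), c("case_id", "slice_index", "label"))

## middle slice_index value of one case's rows
middle_index <- function(slice_indices) {
  s <- sort(slice_indices)
  s[floor((length(s) - 1) / 2) + 1]
}

## Case-level aggregation of slice-level predictions: SINGLE uses the middle
## slice only; ALL votes on hard labels and scores the case by the mean
## slice malignancy score.
aggregate_case <- function(hard, score, strategy) {
  if (strategy == "single" || length(hard) == 1) {
    list(hard = hard[1], score = score[1])
  } else {
    list(hard = vote(hard), score = mean(score))
  }
}

run_fold_svm_stack <- function(tab, train_ids, test_ids, strategy, svm,
                               select = NULL, fold_seed = 1L) {
  fc <- feature_cols(tab)
  train_tab <- tab[tab$case_id %in% train_ids, , drop = FALSE]
  if (strategy == "single" && !all(is.na(tab$slice_index))) {
    keep <- unlist(lapply(split(seq_len(nrow(train_tab)), train_tab$case_id),
                          function(ix) {
                            ix[train_tab$slice_index[ix] ==
                                 middle_index(train_tab$slice_index[ix])][1]
                          }))
    train_tab <- train_tab[keep, , drop = FALSE]
  }
  feats <- fc
  if (!is.null(select)) {
    sel <- bootstrap_select(train_tab[, fc, drop = FALSE], train_tab$label,
                            B = select$B, k = select$k, tau = select$tau,
                            seed = fold_seed)
    if (length(sel) >= 2) feats <- sel
  }
  clf <- suppressWarnings(
    fit_svm(train_tab[, feats, drop = FALSE], train_tab$label, svm))
  test_tab <- tab[tab$case_id %in% test_ids, , drop = FALSE]
  pr <- predict_scores(clf, test_tab[, feats, drop = FALSE])
  res <- lapply(test_ids, function(id) {
    ix <- which(test_tab$case_id == id)
    if (!all(is.na(test_tab$slice_index))) {
      ord <- order(test_tab$slice_index[ix]); ix <- ix[ord]
      if (strategy == "single" && length(ix) > 1) {
        ix <- ix[floor((length(ix) - 1) / 2) + 1]
      }
    }
    aggregate_case(pr$hard_label[ix], pr$score[ix], strategy)
  })
  list(hard = vapply(res, `[[`, character(1), "hard"),
       score = vapply(res, `[[`, numeric(1), "score"))
}

run_fold_sdae <- function(records, train_ids, test_ids, strategy,
                          pre_spec, fine_spec, fold_seed) {
  by_id <- stats::setNames(records, vapply(records, function(r) r$case_id,
                                           character(1)))
  train_recs <- by_id[train_ids]
  train_samples <- if (strategy == "all") {
    withr::with_seed(fold_seed, expand_all(train_recs))
  } else {
    lapply(train_recs, select_single)
  }
  pre <- sdae_pretrain(train_samples,
                       train_spec(pre_spec$learning_rate, pre_spec$epochs,
                                  pre_spec$batch_size, seed = fold_seed))
  model <- sdae_finetune(pre, train_samples,
                         train_spec(fine_spec$learning_rate, fine_spec$epochs,
                                    fine_spec$batch_size, seed = fold_seed + 1L))
  res <- lapply(test_ids, function(id) {
    rec <- by_id[[id]]
    slices <- if (strategy == "single") list(select_single(rec)) else rec$slices
    pred <- sdae_predict(model, slices)
    aggregate_case(pred$hard_label, pred$p_malignant, strategy)
  })
  list(hard = vapply(res, `[[`, character(1), "hard"),
       score = vapply(res, `[[`, numeric(1), "score"))
}

#' Run the full cross-validated CADx comparison
#'
#' For every repetition and fold of the shared `fold_plan`, trains each
#' requested method on the training cases (under the chosen slice-selection
#' strategy) and evaluates it at the case level on the test cases, recording
#' the six metrics per fold. All methods reuse the identical partitions. A
#' leakage assertion verifies that no case id ever appears on both sides of
#' a split.
#'
#' @param x List of `synth_case` objects or the path to a manifest CSV.
#' @param methods Subset of `c("sdae", "rank", "curve", "morph")`.
#' @param strategy `"single"` (middle slice) or `"all"` (all member slices
#'   with majority voting at test time). MORPH features are inherently
#'   case-level and ignore the strategy.
#' @param plan A [make_folds()] plan covering exactly the cases of `x`.
#' @param roi_margin Crop margin around the mask bounding box.
#' @param svm [svm_spec()] shared by the baseline stacks.
#' @param rank_select Bootstrap-selection settings for the RANK stack as
#'   `list(B, k, tau)`, or `NULL` to disable selection.
#' @param pre_spec,fine_spec [train_spec()]s for SDAE pretraining and
#'   fine-tuning (seeds are derived per fold from the plan seed).
#' @return Object of class `cadx_report`: `per_fold` data.frame (one row per
#'   method x repetition x fold) and `summary` (mean and sd per method and
#'   metric, NA folds excluded).
#' @export
run_experiment <- function(x,
                           methods = c("morph"),
                           strategy = c("single", "all"),
                           plan,
                           roi_margin = 0.25,
                           svm = svm_spec(),
                           rank_select = list(B = 30L, k = 12L, tau = 0.5),
                           pre_spec = train_spec(0.1, 15L, 20L),
                           fine_spec = train_spec(0.05, 100L, 20L)) {
  strategy <- match.arg(strategy)
  methods <- match.arg(methods, c("sdae", "rank", "curve", "morph"),
                       several.ok = TRUE)
  cases <- if (is.character(x)) read_manifest(x) else x
  ids <- vapply(cases, function(cs) cs$case_id, character(1))
  if (!setequal(ids, plan$case_ids)) {
    stop_input("fold plan does not cover the cases of this dataset")
  }
  labels <- stats::setNames(vapply(cases, function(cs) cs$label, character(1)),
                            ids)

  tabs <- list()
  for (m in intersect(methods, c("rank", "curve", "morph"))) {
    tabs[[m]] <- extract_features(cases, m, roi_margin)
  }
  records <- if ("sdae" %in% methods) prepare_case_records(cases, roi_margin)

  rows <- list()
  for (r in seq_along(plan$repetitions)) {
    folds <- plan$repetitions[[r]]
    for (f in seq_along(folds)) {
      test_ids <- folds[[f]]
      train_ids <- setdiff(ids, test_ids)
      if (length(intersect(train_ids, test_ids)) > 0) {
        stop("case leakage between train and test folds") # never tolerated
      }
      fold_seed <- (plan$seed %% 10000L) * 100000L + r * 1000L + f
      truth <- unname(labels[test_ids])
      for (m in methods) {
        out <- if (m == "sdae") {
          run_fold_sdae(records, train_ids, test_ids, strategy,
                        pre_spec, fine_spec, fold_seed)
        } else {
          run_fold_svm_stack(tabs[[m]], train_ids, test_ids,
                             if (m == "morph") "single" else strategy,
                             svm,
                             select = if (m == "rank") rank_select,
                             fold_seed = fold_seed)
        }
        met <- six_metrics(truth, out$hard, out$score)
        rows[[length(rows) + 1]] <- data.frame(
          method = m, repetition = r, fold = f, n_test = length(test_ids),
          t(met), stringsAsFactors = FALSE)
      }
    }
  }
  per_fold <- do.call(rbind, rows)
  metric_names <- c("AUC", "ACC", "SENS", "SPEC", "PPV", "NPV")
  summary <- do.call(rbind, lapply(split(per_fold, per_fold$method), function(d) {
    data.frame(method = d$method[1],
               metric = metric_names,
               mean = vapply(metric_names, function(mn) mean(d[[mn]], na.rm = TRUE),
                             numeric(1)),
               sd = vapply(metric_names, function(mn) stats::sd(d[[mn]], na.rm = TRUE),
                           numeric(1)),
               row.names = NULL)
  }))
  structure(list(per_fold = per_fold, summary = summary, strategy = strategy,
                 plan_seed = plan$seed),
            class = "cadx_report")
}

#' @export
print.cadx_report <- function(x, ...) {
  cat("cadx_report:", nrow(x$per_fold), "fold rows, strategy", x$strategy, "\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Pairwise method comparison on a per-fold metric
#'
#' Bland-Altman agreement and a pooled-variance two-sample t-test between
#' every pair of methods in a report, paired/compared over the per-fold
#' values of one metric.
#'
#' @param report A [run_experiment()] result.
#' @param metric One of `"AUC"`, `"ACC"`, `"SENS"`, `"SPEC"`, `"PPV"`,
#'   `"NPV"`.
#' @return data.frame with one row per method pair (`mean_diff`, limits,
#'   `t`, `p_value`) and the `bland_altman` objects as attribute
#'   `"bland_altman"`.
#' @export
compare_methods <- function(report, metric = "ACC") {
  pf <- report$per_fold
  methods <- unique(pf$method)
  if (length(methods) < 2) stop_input("need at least two methods to compare")
  pairs <- utils::combn(methods, 2, simplify = FALSE)
  bas <- list()
  rows <- lapply(pairs, function(p) {
    a <- pf[pf$method == p[1], metric]
    b <- pf[pf$method == p[2], metric]
    ok <- is.finite(a) & is.finite(b)
    ba <- bland_altman(a[ok], b[ok])
    tt <- two_sample_t(a[ok], b[ok])
    bas[[paste(p, collapse = "-")]] <<- ba
    data.frame(method_a = p[1], method_b = p[2], metric = metric,
               mean_diff = ba$mean_diff, lower_limit = ba$lower_limit,
               upper_limit = ba$upper_limit, t = tt$t, p_value = tt$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "bland_altman") <- bas
  out
}
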