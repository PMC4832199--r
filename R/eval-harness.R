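## Evaluation protocol: repeated stratified 10-fold cross-validation at the
## case level with partitions shared across methods, six diagnostic metrics
## per fold, Bland-Altman agreement between methods and two-sample t-tests.

## Tie-corrected rank AUC (Mann-Whitney U / (n1 n0)); pos is logical.
rank_auc <- function(scores, pos) {
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  rk <- rank(scores)
  (sum(rk[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Six diagnostic performance metrics
#'
#' Malignant is the positive class. ACC, SENS, SPEC, PPV and NPV follow the
#' usual confusion-matrix definitions; AUC is the tie-corrected rank
#' statistic over `scores` (equal to Mann-Whitney U / (n1 n0)). Ratios with
#' a zero denominator are reported as `NA`, not 0.
#'
#' @param labels True labels, `"benign"`/`"malignant"`.
#' @param hard_preds Predicted hard labels.
#' @param scores Numeric malignancy scores (larger = more malignant); may be
#'   `NULL`, in which case AUC is `NA`.
#' @return Named numeric vector `(AUC, ACC, SENS, SPEC, PPV, NPV)`.
#' @examples
#' six_metrics(rep(c("malignant", "benign"), c(10, 10)),
#'             rep(c("malignant", "benign", "malignant", "benign"),
#'                 c(9, 1, 2, 8)))
#' @export
six_metrics <- function(labels, hard_preds, scores = NULL) {
  if (!length(labels)) stop_input("empty evaluation set")
  pos <- labels == "malignant"
  pred_pos <- hard_preds == "malignant"
  tp <- sum(pos & pred_pos); fn <- sum(pos & !pred_pos)
  tn <- sum(!pos & !pred_pos); fp <- sum(!pos & pred_pos)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  c(AUC = if (is.null(scores)) NA_real_ else rank_auc(scores, pos),
    ACC = ratio(tp + tn, length(labels)),
    SENS = ratio(tp, tp + fn),
    SPEC = ratio(tn, tn + fp),
    PPV = ratio(tp, tp + fp),
    NPV = ratio(tn, tn + fn))
}

## Canonical signature of a partition (order of folds and of ids within a
## fold must not matter when checking distinctness).
partition_signature <- function(folds) {
  paste(sort(vapply(folds, function(f) paste(sort(f), collapse = ","),
                    character(1))), collapse = "|")
}

#' Repeated stratified k-fold partitions at the case level
#'
#' Each repetition partitions all case ids into `n_folds` disjoint test
#' sets, stratified by class so fold class balance matches the data set.
#' Repetitions are guaranteed pairwise-distinct partitions (redrawn on
#' collision). Keeping whole cases on one side of every split means no
#' slice of a test case is ever seen in training.
#'
#' @param case_ids Character vector of unique case ids.
#' @param labels Matching `"benign"`/`"malignant"` labels.
#' @param n_folds Folds per repetition (default 10).
#' @param repetitions Number of repetitions (default 10).
#' @param seed Integer seed.
#' @return Object of class `fold_plan`: list with `repetitions` (list of
#'   lists of test-id vectors), `case_ids`, `labels`, `seed`.
#' @export
make_folds <- function(case_ids, labels, n_folds = 10L, repetitions = 10L,
                       seed = 1L) {
  if (anyDuplicated(case_ids)) stop_input("case ids must be unique")
  if (length(case_ids) < 2 * n_folds) {
    stop_input("need at least ", 2 * n_folds, " cases for ", n_folds, " folds")
  }
  if (length(unique(labels)) < 2) stop_input("both classes must be present")
  if (min(table(labels)) < n_folds) {
    stop_input("too few cases in one class for stratified ", n_folds, "-fold CV")
  }
  withr::with_seed(seed, {
    draw <- function() {
      folds <- replicate(n_folds, character(0), simplify = FALSE)
      pos <- 0L # continue the round-robin across classes to balance totals
      for (cl in unique(labels)) {
        ids <- sample(case_ids[labels == cl])
        bins <- ((pos + seq_along(ids) - 1L) %% n_folds) + 1L
        for (f in seq_len(n_folds)) {
          folds[[f]] <- c(folds[[f]], ids[bins == f])
        }
        pos <- pos + length(ids)
      }
      folds
    }
    reps <- list(); sigs <- character(0)
    for (r in seq_len(repetitions)) {
      for (try in 1:1000) {
        folds <- draw()
        sig <- partition_signature(folds)
        if (!sig %in% sigs) break
        if (try == 1000) stop_input("cannot draw distinct partitions")
      }
      sigs <- c(sigs, sig)
      reps[[r]] <- folds
    }
    structure(list(repetitions = reps, case_ids = case_ids, labels = labels,
                   n_folds = as.integer(n_folds), seed = as.integer(seed)),
              class = "fold_plan")
  })
}

#' @export
print.fold_plan <- function(x, ...) {
  cat("fold_plan:", length(x$repetitions), "repetitions x", x$n_folds,
      "folds over", length(x$case_ids), "cases (seed", x$seed, ")\n")
  invisible(x)
}

#' Serialize / load a fold plan so all methods share identical partitions
#'
#' @param plan A `fold_plan`.
#' @param path JSON file path.
#' @return `write_fold_plan` returns `path` invisibly; `read_fold_plan` the
#'   restored `fold_plan`.
#' @export
write_fold_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fold_plan
#' @export
read_fold_plan <- function(path) {
  x <- jsonlite::read_json(path)
  structure(list(
    repetitions = lapply(x$repetitions, function(r) {
      lapply(r, function(f) vapply(f, as.character, character(1),
                                   USE.NAMES = FALSE))
    }),
    case_ids = vapply(x$case_ids, as.character, character(1), USE.NAMES = FALSE),
    labels = vapply(x$labels, as.character, character(1), USE.NAMES = FALSE),
    n_folds = as.integer(x$n_folds),
    seed = as.integer(x$seed)), class = "fold_plan")
}

#' Bland-Altman agreement statistics between two paired metric series
#'
#' Differences are `a - b`; the limits of agreement are the mean difference
#' plus/minus 1.96 sample standard deviations.
#'
#' @param a,b Equal-length numeric vectors paired by fold.
#' @return Object of class `bland_altman` with `mean_diff`, `sd_diff`,
#'   `upper_limit`, `lower_limit` and a `pairs` data.frame (per-fold mean
#'   and difference, ready for plotting).
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop_input("inputs must be paired (equal length)")
  d <- a - b
  m <- mean(d)
  s <- if (length(d) > 1) stats::sd(d) else 0
  structure(list(mean_diff = m, sd_diff = s,
                 upper_limit = m + 1.96 * s, lower_limit = m - 1.96 * s,
                 pairs = data.frame(mean = (a + b) / 2, diff = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: mean diff %.4f, limits [%.4f, %.4f]\n",
              x$mean_diff, x$lower_limit, x$upper_limit))
  invisible(x)
}

#' Two-sample pooled-variance t-test on per-fold metric values
#'
#' Two-sided Student t-test assuming equal variances. A zero pooled variance
#' with equal means returns `t = 0, p = 1` by convention (identical constant
#' series agree perfectly).
#'
#' @param a,b Numeric vectors of length >= 2.
#' @return List with `t`, `df`, `p_value`.
#' @export
two_sample_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop_input("each sample needs length >= 2")
  pooled <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  df <- length(a) + length(b) - 2
  if (pooled == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = df, p_value = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = df, p_value = 0))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}
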