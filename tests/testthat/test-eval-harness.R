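test_that("six metrics reproduce the confusion-matrix hand check", {
  labels <- rep(c("malignant", "benign"), c(10, 10))
  preds <- c(rep("malignant", 9), "benign",          # TP = 9, FN = 1
             rep("malignant", 2), rep("benign", 8))  # FP = 2, TN = 8
  m <- six_metrics(labels, preds)
  expect_equal(unname(m["ACC"]), 0.85)
  expect_equal(unname(m["SENS"]), 0.90)
  expect_equal(unname(m["SPEC"]), 0.80)
  expect_equal(unname(m["PPV"]), 9 / 11)
  expect_equal(unname(m["NPV"]), 8 / 9)
})

test_that("rank AUC equals the all-pairs statistic with tie credit", {
  labels <- rep(c("malignant", "benign"), each = 5)
  perfect <- c(6:10, 1:5)
  expect_equal(unname(six_metrics(labels, labels, perfect)["AUC"]), 1)
  expect_equal(unname(six_metrics(labels, labels, -perfect)["AUC"]), 0)
  withr::with_seed(70, {
    for (i in 1:20) {
      n <- sample(8:30, 1)
      lab <- sample(rep(c("malignant", "benign"), length.out = n))
      sc <- sample(1:6, n, replace = TRUE) # heavy ties
      expect_equal(unname(six_metrics(lab, lab, sc)["AUC"]),
                   brute_auc(sc, lab == "malignant"), tolerance = 1e-12)
    }
    ## independent library cross-check on a continuous-score case
    lab <- sample(rep(c("malignant", "benign"), 15))
    sc <- rnorm(30)
    expect_equal(unname(six_metrics(lab, lab, sc)["AUC"]),
                 as.numeric(pROC::auc(pROC::roc(
                   response = lab, predictor = sc, levels = c("benign", "malignant"),
                   direction = "<", quiet = TRUE))),
                 tolerance = 1e-12)
  })
})

test_that("zero-denominator ratios are reported missing, not zero", {
  labels <- rep("malignant", 5)
  m <- six_metrics(labels, rep("malignant", 5))
  expect_true(is.na(m["SPEC"]) && is.na(m["NPV"]) && is.na(m["AUC"]))
  expect_equal(unname(m["SENS"]), 1)
  ## constant benign predictor: SENS 0, SPEC 1, PPV undefined
  lab2 <- rep(c("malignant", "benign"), 5)
  m2 <- six_metrics(lab2, rep("benign", 10))
  expect_equal(unname(m2["SENS"]), 0)
  expect_equal(unname(m2["SPEC"]), 1)
  expect_true(is.na(m2["PPV"]))
})

test_that("fold plans partition cases, stratify classes and stay distinct", {
  ids <- sprintf("c%03d", 1:520)
  labels <- rep(c("benign", "malignant"), c(275, 245))
  plan <- make_folds(ids, labels, seed = 3)
  expect_length(plan$repetitions, 10)
  for (rep_folds in plan$repetitions) {
    expect_length(rep_folds, 10)
    sizes <- lengths(rep_folds)
    expect_true(all(sizes == 52)) # 520 cases -> 52 per test fold
    expect_setequal(unlist(rep_folds), ids)
    expect_equal(anyDuplicated(unlist(rep_folds)), 0)
    ## stratification: each fold close to the global 275/245 split
    for (f in rep_folds) {
      nb <- sum(labels[match(f, ids)] == "benign")
      expect_true(abs(nb - 27.5) <= 1)
    }
  }
  sigs <- vapply(plan$repetitions, sdaecadx:::partition_signature, character(1))
  expect_equal(anyDuplicated(sigs), 0)
  expect_identical(make_folds(ids, labels, seed = 3), plan)
  expect_error(make_folds(ids[1:15], labels[1:15], n_folds = 10), "at least")
})

test_that("fold plans serialize losslessly to JSON", {
  ids <- sprintf("k%02d", 1:40)
  labels <- rep(c("benign", "malignant"), 20)
  plan <- make_folds(ids, labels, n_folds = 4, repetitions = 3, seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  write_fold_plan(plan, path)
  back <- read_fold_plan(path)
  expect_equal(back$repetitions, plan$repetitions)
  expect_equal(back$seed, plan$seed)
})

test_that("Bland-Altman limits follow the 1.96-sd closed form", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba0$mean_diff, 0)
  expect_equal(ba0$upper_limit, 0)
  expect_equal(ba0$lower_limit, 0)
  ba <- bland_altman(c(1, 0), c(0, 1)) # diffs +1, -1
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, sqrt(2))
  expect_equal(ba$upper_limit, 1.96 * sqrt(2))
  withr::with_seed(71, {
    a <- runif(20); b <- runif(20)
    got <- bland_altman(a, b)
    d <- a - b
    expect_equal(got$mean_diff, sum(d) / 20, tolerance = 1e-12)
    expect_equal(got$sd_diff, sqrt(sum((d - mean(d))^2) / 19), tolerance = 1e-12)
    expect_equal(got$upper_limit, got$mean_diff + 1.96 * got$sd_diff)
    expect_equal(got$pairs$mean, (a + b) / 2)
  })
  expect_error(bland_altman(1:3, 1:4), "paired")
})

test_that("the two-sample t-test matches the pooled-variance hand computation", {
  tt <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$t, -3.674, tolerance = 1e-3)
  expect_equal(tt$df, 4)
  ## identical samples: t = 0, p = 1 even with zero variance
  same <- two_sample_t(c(2, 2), c(2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  ## symmetry under swapping
  a <- c(0.8, 0.85, 0.9); b <- c(0.7, 0.75, 0.72)
  expect_equal(two_sample_t(a, b)$p_value, two_sample_t(b, a)$p_value)
  expect_equal(two_sample_t(a, b)$t, -two_sample_t(b, a)$t)
  expect_error(two_sample_t(1, c(1, 2)), "length")
})

test_that("the experiment driver produces leak-free per-fold reports", {
  cases <- tiny_ct_cases(12, seed = 72, slices = c(2L, 4L))
  ids <- vapply(cases, function(x) x$case_id, character(1))
  labels <- vapply(cases, function(x) x$label, character(1))
  plan <- make_folds(ids, labels, n_folds = 4, repetitions = 2, seed = 4)
  rep <- run_experiment(cases, methods = "morph", strategy = "all", plan = plan)
  expect_equal(nrow(rep$per_fold), 2 * 4)
  expect_true(all(rep$per_fold$n_test == 6))
  mets <- rep$per_fold[, c("AUC", "ACC", "SENS", "SPEC", "PPV", "NPV")]
  expect_true(all(is.na(mets) | (mets >= 0 & mets <= 1)))
  ## summary equals brute-force recomputation from the per-fold table
  for (i in seq_len(nrow(rep$summary))) {
    r <- rep$summary[i, ]
    vals <- rep$per_fold[rep$per_fold$method == r$method, r$metric]
    expect_equal(r$mean, mean(vals, na.rm = TRUE), tolerance = 1e-12)
    expect_equal(r$sd, sd(vals, na.rm = TRUE), tolerance = 1e-12)
  }
  ## a plan over different cases is rejected
  plan_bad <- make_folds(paste0("x", 1:40),
                         rep(c("benign", "malignant"), 20),
                         n_folds = 4, repetitions = 2, seed = 4)
  expect_error(run_experiment(cases, methods = "morph", plan = plan_bad),
               "cover")
})

test_that("SINGLE and ALL agree on single-slice data", {
  cases <- tiny_ct_cases(10, seed = 73, slices = c(1L, 1L))
  ids <- vapply(cases, function(x) x$case_id, character(1))
  labels <- vapply(cases, function(x) x$label, character(1))
  plan <- make_folds(ids, labels, n_folds = 4, repetitions = 2, seed = 5)
  r_single <- run_experiment(cases, methods = "curve", strategy = "single",
                             plan = plan)
  r_all <- run_experiment(cases, methods = "curve", strategy = "all",
                          plan = plan)
  expect_equal(r_single$per_fold[, -ncol(r_single$per_fold)],
               r_all$per_fold[, -ncol(r_all$per_fold)],
               ignore_attr = TRUE)
})

test_that("method comparison reports agreement and significance per pair", {
  cases <- tiny_ct_cases(12, seed = 74, slices = c(2L, 3L))
  ids <- vapply(cases, function(x) x$case_id, character(1))
  labels <- vapply(cases, function(x) x$label, character(1))
  plan <- make_folds(ids, labels, n_folds = 4, repetitions = 2, seed = 6)
  rep <- run_experiment(cases, methods = c("morph", "curve"), strategy = "all",
                        plan = plan)
  cmp <- compare_methods(rep, "ACC")
  expect_equal(nrow(cmp), 1)
  ba <- attr(cmp, "bland_altman")[[1]]
  expect_equal(cmp$upper_limit, ba$mean_diff + 1.96 * ba$sd_diff)
  a <- rep$per_fold[rep$per_fold$method == cmp$method_a, "ACC"]
  b <- rep$per_fold[rep$per_fold$method == cmp$method_b, "ACC"]
  expect_equal(cmp$mean_diff, mean(a - b), tolerance = 1e-12)
})
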