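## SVM classifier stage shared by the RANK, CURVE and MORPH baselines.
## Thin, deterministic wrapper around e1071::svm (libsvm) with training-set
## standardization and decision scores oriented so that larger = more
## malignant.

#' SVM settings for the baseline classifiers
#'
#' @param kernel `"radial"` or `"linear"`.
#' @param C Soft-margin cost.
#' @param gamma RBF width, or `"scale"` for `1 / (d * var(X))` fitted on the
#'   training features.
#' @param standardize Z-score features with training statistics.
#' @return An object of class `svm_spec`.
#' @export
svm_spec <- function(kernel = c("radial", "linear"), C = 1, gamma = "scale",
                     standardize = TRUE) {
  kernel <- match.arg(kernel)
  if (C <= 0) stop_input("C must be positive")
  if (!identical(gamma, "scale") && (!is.numeric(gamma) || gamma <= 0)) {
    stop_input("gamma must be positive or 'scale'")
  }
  structure(list(kernel = kernel, C = C, gamma = gamma,
                 standardize = standardize),
            class = "svm_spec")
}

#' Fit the baseline SVM on a feature table
#'
#' Constant feature columns are dropped with a warning; remaining features
#' are optionally z-scored with training statistics. Decision values are
#' exposed via [predict_scores()] with the malignant class on the positive
#' side.
#'
#' @param X Feature matrix or data.frame (rows = samples, named columns).
#' @param y Labels `"benign"`/`"malignant"` (both must occur).
#' @param spec An [svm_spec()].
#' @return An object of class `cadx_svm`.
#' @export
fit_svm <- function(X, y, spec = svm_spec()) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (length(unique(y)) < 2) stop_input("training labels must contain both classes")
  if (any(!is.finite(X))) stop_input("features must be finite")
  keep <- apply(X, 2, function(col) stats::sd(col) > 0)
  if (!all(keep)) {
    warning("dropping constant feature column(s): ",
            paste(colnames(X)[!keep], collapse = ", "), call. = FALSE)
    X <- X[, keep, drop = FALSE]
  }
  if (ncol(X) == 0) stop_input("no informative features left")
  ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  if (spec$standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    X <- scale(X, center = ctr, scale = scl)
  }
  gamma <- if (identical(spec$gamma, "scale")) {
    v <- stats::var(as.vector(X))
    if (v > 0) 1 / (ncol(X) * v) else 1 / ncol(X)
  } else spec$gamma
  yf <- factor(y, levels = c("benign", "malignant"))
  fit <- e1071::svm(x = X, y = yf, kernel = spec$kernel, cost = spec$C,
                    gamma = gamma, scale = FALSE)
  structure(list(fit = fit, features = colnames(X), center = ctr, scale = scl,
                 spec = spec),
            class = "cadx_svm")
}

#' Decision scores and hard labels from a fitted baseline SVM
#'
#' @param clf A [fit_svm()] result.
#' @param X Feature matrix/data.frame with the training feature columns.
#' @return data.frame with `score` (larger = more malignant) and
#'   `hard_label`.
#' @export
predict_scores <- function(clf, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  miss <- setdiff(clf$features, colnames(X))
  if (length(miss)) {
    stop_input("missing feature column(s): ", paste(miss, collapse = ", "))
  }
  X <- X[, clf$features, drop = FALSE]
  if (clf$spec$standardize) X <- scale(X, center = clf$center, scale = clf$scale)
  pr <- stats::predict(clf$fit, X, decision.values = TRUE)
  dv <- drop(attr(pr, "decision.values"))
  ## libsvm signs decision values towards the first training class seen;
  ## orient them so positive = malignant
  flip <- if (grepl("^malignant", colnames(attr(pr, "decision.values"))[1])) 1 else -1
  data.frame(score = flip * as.numeric(dv),
             hard_label = as.character(pr),
             stringsAsFactors = FALSE)
}
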