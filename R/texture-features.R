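## Texture feature stacks for the conventional CADx baselines: gray-level
## co-occurrence matrices with the 14 classic Haralick statistics, the
## rank-based (Mann-Whitney) ranklet transform, a pluggable sub-band
## decomposition with a separable Haar wavelet default, angle averaging and
## bootstrap feature selection.

#' GLCM computation settings
#'
#' @param levels Number of gray levels after quantization (>= 2).
#' @param distances Pixel offsets at which pairs are counted.
#' @param angles Subset of `c(0, 45, 90, 135)` degrees.
#' @param symmetric Add the transposed counts (order-independent pairs).
#' @param normalized Normalize counts to sum to 1.
#' @return An object of class `glcm_spec`.
#' @export
glcm_spec <- function(levels = 16L, distances = 1L,
                      angles = c(0, 45, 90, 135),
                      symmetric = TRUE, normalized = TRUE) {
  if (!is_count(levels) || levels < 2) stop_input("levels must be an integer >= 2")
  if (any(distances < 1)) stop_input("distances must be >= 1")
  if (!all(angles %in% c(0, 45, 90, 135))) {
    stop_input("angles must be in {0, 45, 90, 135}")
  }
  structure(list(levels = as.integer(levels), distances = as.integer(distances),
                 angles = angles, symmetric = symmetric, normalized = normalized),
            class = "glcm_spec")
}

#' Quantize a [0,1] image to discrete gray levels
#'
#' Uniform binning: level `floor(x * levels)`, with 1.0 clamped into the top
#' bin. Returns integer levels in `0 .. levels-1`.
#'
#' @param img Matrix with values in `[0, 1]`.
#' @param levels Number of bins.
#' @export
quantize_gray <- function(img, levels = 16L) {
  matrix(pmin(floor(img * levels), levels - 1L), nrow(img), ncol(img))
}

## Row/col displacement of one co-occurrence step. Angles follow the usual
## convention of measuring counter-clockwise from the positive x axis in
## image coordinates (row increases downwards): 0 deg pairs a pixel with its
## right neighbour, 90 deg with the pixel above.
angle_offset <- function(angle, d) {
  switch(as.character(angle),
         "0" = c(0L, d), "45" = c(-d, d), "90" = c(-d, 0L), "135" = c(-d, -d),
         stop_input("angle must be one of 0, 45, 90, 135"))
}

#' Gray-level co-occurrence matrix
#'
#' Counts ordered pairs of quantized levels separated by the displacement of
#' `(distance, angle)`; with `symmetric = TRUE` the transpose is added so
#' pair order is ignored, and with `normalized = TRUE` the matrix is scaled
#' to sum to 1.
#'
#' @param img Integer matrix with values in `0 .. levels-1` (see
#'   [quantize_gray()]).
#' @param spec A [glcm_spec()].
#' @param distance Pixel offset (defaults to the first of `spec$distances`).
#' @param angle One of 0, 45, 90, 135 degrees.
#' @return `levels` x `levels` matrix.
#' @export
glcm <- function(img, spec = glcm_spec(), distance = spec$distances[1],
                 angle = spec$angles[1]) {
  L <- spec$levels
  if (any(img < 0) || any(img >= L)) {
    stop_input("image values must lie in [0, levels)")
  }
  off <- angle_offset(angle, distance)
  nr <- nrow(img); nc <- ncol(img)
  r <- seq_len(nr); c <- seq_len(nc)
  rsrc <- r[r + off[1] >= 1 & r + off[1] <= nr]
  csrc <- c[c + off[2] >= 1 & c + off[2] <= nc]
  P <- matrix(0, L, L)
  if (length(rsrc) && length(csrc)) {
    a <- img[rsrc, csrc, drop = FALSE]
    b <- img[rsrc + off[1], csrc + off[2], drop = FALSE]
    counts <- table(factor(a, levels = 0:(L - 1)),
                    factor(b, levels = 0:(L - 1)))
    P <- matrix(as.numeric(counts), L, L)
  }
  if (spec$symmetric) P <- P + t(P)
  if (spec$normalized && sum(P) > 0) P <- P / sum(P)
  P
}

haralick_names <- c(
  "energy", "contrast", "correlation", "variance",
  "inverse_difference_moment", "sum_average", "sum_variance", "sum_entropy",
  "entropy", "difference_variance", "difference_entropy",
  "info_correlation_1", "info_correlation_2", "max_correlation_coef")

## 12-feature subset used by the ranklet stack (drops the two heaviest /
## least stable statistics: sum variance and the maximal correlation
## coefficient).
haralick_names_12 <- setdiff(haralick_names,
                             c("sum_variance", "max_correlation_coef"))

xlogx <- function(p) ifelse(p > 0, p * log(p), 0)

#' The 14 classic Haralick texture features of a normalized GLCM
#'
#' Energy (angular second moment), contrast, correlation, variance (sum of
#' squares), inverse difference moment, sum average/variance/entropy,
#' entropy, difference variance/entropy, the two information measures of
#' correlation, and the maximal correlation coefficient. Entropies use the
#' natural logarithm; degenerate marginals (zero variance) yield 0 for
#' correlation-type features by convention.
#'
#' @param P Normalized (sum 1) GLCM, typically symmetric.
#' @param subset Optional character vector of feature names to keep, e.g.
#'   the built-in 12-feature subset used by the ranklet stack.
#' @return Named numeric vector.
#' @export
haralick <- function(P, subset = NULL) {
  if (abs(sum(P) - 1) > 1e-8) stop_input("GLCM must be normalized to sum 1")
  L <- nrow(P)
  i <- matrix(seq_len(L), L, L)          # row level index (1-based)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(L) * px); muy <- sum(seq_len(L) * py)
  sdx <- sqrt(sum((seq_len(L) - mux)^2 * px))
  sdy <- sqrt(sum((seq_len(L) - muy)^2 * py))

  ## p_{x+y}(k), k = 2..2L and p_{x-y}(k), k = 0..L-1
  psum <- vapply(2:(2 * L), function(k) sum(P[i + j == k]), numeric(1))
  kd <- 0:(L - 1)
  pdiff <- vapply(kd, function(k) sum(P[abs(i - j) == k]), numeric(1))

  energy <- sum(P^2)
  contrast <- sum(kd^2 * pdiff)
  correlation <- if (sdx > 0 && sdy > 0) {
    (sum(i * j * P) - mux * muy) / (sdx * sdy)
  } else 0
  variance <- sum((i - mux)^2 * P)
  idm <- sum(P / (1 + (i - j)^2))
  ks <- 2:(2 * L)
  sum_average <- sum(ks * psum)
  sum_variance <- sum((ks - sum_average)^2 * psum)
  sum_entropy <- -sum(xlogx(psum))
  entropy <- -sum(xlogx(P))
  diff_mean <- sum(kd * pdiff)
  difference_variance <- sum((kd - diff_mean)^2 * pdiff)
  difference_entropy <- -sum(xlogx(pdiff))

  hx <- -sum(xlogx(px)); hy <- -sum(xlogx(py))
  PXY <- outer(px, py)
  hxy1 <- -sum(P * ifelse(PXY > 0, log(PXY), 0))
  hxy2 <- -sum(xlogx(PXY))
  ic1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  ic2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy))))

  ## maximal correlation coefficient: sqrt of the second-largest eigenvalue
  ## of Q with Q_ij = sum_k P(i,k) P(j,k) / (px_i py_k)
  pos <- px > 0 & py > 0
  mcc <- 0
  if (sum(pos) >= 2) {
    Ppos <- P[pos, pos, drop = FALSE]
    Q <- (Ppos / px[pos]) %*% (t(Ppos) / py[pos])
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- sqrt(max(0, ev[2]))
  }

  out <- c(energy, contrast, correlation, variance, idm, sum_average,
           sum_variance, sum_entropy, entropy, difference_variance,
           difference_entropy, ic1, ic2, mcc)
  names(out) <- haralick_names
  if (!is.null(subset)) {
    miss <- setdiff(subset, haralick_names)
    if (length(miss)) stop_input("unknown features: ", paste(miss, collapse = ", "))
    out <- out[subset]
  }
  out
}

## ---------------------------------------------------------------- ranklet

#' Ranklet transform settings
#'
#' @param window_sizes Even window side lengths (>= 2).
#' @param orientations Subset of `c("vertical", "horizontal", "diagonal")`.
#' @return An object of class `ranklet_spec`.
#' @export
ranklet_spec <- function(window_sizes = c(4L, 8L),
                         orientations = c("vertical", "horizontal", "diagonal")) {
  if (any(window_sizes %% 2 != 0) || any(window_sizes < 2)) {
    stop_input("window sizes must be even and >= 2")
  }
  orientations <- match.arg(orientations,
                            c("vertical", "horizontal", "diagonal"),
                            several.ok = TRUE)
  structure(list(window_sizes = as.integer(window_sizes),
                 orientations = orientations),
            class = "ranklet_spec")
}

## Haar-style split of a w x w window into treatment (TRUE) / control halves.
ranklet_split <- function(w, orientation) {
  half <- w / 2
  switch(orientation,
         vertical = matrix(rep(c(FALSE, TRUE), each = w * half), w, w),
         horizontal = matrix(rep(c(TRUE, FALSE), each = half), w, w),
         diagonal = {
           m <- matrix(FALSE, w, w)
           m[1:half, 1:half] <- TRUE          # NW
           m[(half + 1):w, (half + 1):w] <- TRUE # SE
           m
         })
}

## Mann-Whitney response of one window: 2 U / (nT nC) - 1 in [-1, 1], with
## midranks so ties contribute 1/2. U = sum of treatment ranks - nT(nT+1)/2.
ranklet_window <- function(vals, treat) {
  rk <- rank(vals)                        # midranks handle ties
  nt <- sum(treat); nc <- length(vals) - nt
  U <- sum(rk[treat]) - nt * (nt + 1) / 2
  2 * U / (nt * nc) - 1
}

#' Ranklet transform
#'
#' Rank-based, Haar-like orientation-selective transform: at every position
#' where the full window fits, the window is split into treatment and
#' control halves according to the orientation, and the response is the
#' rescaled Mann-Whitney statistic `2U/(nT nC) - 1` of treatment vs control
#' intensities (ties counted 1/2). Responses lie in `[-1, 1]` and are exactly
#' invariant to any strictly increasing intensity transform.
#'
#' @param img Grayscale matrix.
#' @param spec A [ranklet_spec()].
#' @return Named list of response matrices, one per
#'   `(window size, orientation)`, each of size
#'   `(nrow - w + 1) x (ncol - w + 1)`.
#' @export
ranklet_transform <- function(img, spec = ranklet_spec()) {
  out <- list()
  for (w in spec$window_sizes) {
    if (w > nrow(img) || w > ncol(img)) {
      stop_input("window size ", w, " exceeds image dimensions")
    }
    nr <- nrow(img) - w + 1; nc <- ncol(img) - w + 1
    for (orient in spec$orientations) {
      treat <- as.vector(ranklet_split(w, orient))
      resp <- matrix(0, nr, nc)
      for (r in seq_len(nr)) {
        for (c in seq_len(nc)) {
          vals <- as.vector(img[r:(r + w - 1), c:(c + w - 1)])
          resp[r, c] <- ranklet_window(vals, treat)
        }
      }
      out[[paste0("w", w, "_", orient)]] <- resp
    }
  }
  out
}

## ----------------------------------------------- sub-band decomposition

haar_step <- function(x) {
  n <- length(x)
  odd <- x[seq(1, n, 2)]; even <- x[seq(2, n, 2)]
  c((odd + even), (odd - even)) / sqrt(2)
}

haar_istep <- function(x) {
  n <- length(x); half <- n / 2
  a <- x[1:half]; d <- x[(half + 1):n]
  out <- numeric(n)
  out[seq(1, n, 2)] <- (a + d) / sqrt(2)
  out[seq(2, n, 2)] <- (a - d) / sqrt(2)
  out
}

## One separable 2-D Haar analysis step: returns LL, LH, HL, HH quadrants.
haar_dwt2_step <- function(img) {
  tmp <- t(apply(img, 1, haar_step))       # along columns of each row
  tmp <- apply(tmp, 2, haar_step)          # along rows of each column
  n2r <- nrow(img) / 2; n2c <- ncol(img) / 2
  list(LL = tmp[1:n2r, 1:n2c, drop = FALSE],
       LH = tmp[1:n2r, (n2c + 1):ncol(img), drop = FALSE],
       HL = tmp[(n2r + 1):nrow(img), 1:n2c, drop = FALSE],
       HH = tmp[(n2r + 1):nrow(img), (n2c + 1):ncol(img), drop = FALSE])
}

haar_idwt2_step <- function(LL, LH, HL, HH) {
  tmp <- rbind(cbind(LL, LH), cbind(HL, HH))
  tmp <- apply(tmp, 2, haar_istep)
  t(apply(tmp, 1, haar_istep))
}

#' Sub-band decomposition of an image
#'
#' Pluggable decomposition front-end for the texture pipelines. The default
#' is a 2-level separable orthonormal Haar wavelet transform giving 7 bands
#' (one approximation plus horizontal/vertical/diagonal details at each
#' level); `"identity"` returns the image itself as a single band. Image
#' dimensions must be divisible by `2^levels` for the wavelet method.
#'
#' @param img Grayscale matrix (at least 8x8).
#' @param method `"wavelet"`, `"identity"`, or a function
#'   `img -> named list of bands` plugged in by the caller.
#' @param levels Number of wavelet levels (default 2).
#' @return Named list of sub-band matrices.
#' @export
decompose <- function(img, method = c("wavelet", "identity"), levels = 2L) {
  if (is.function(method)) return(method(img))
  method <- match.arg(method)
  if (nrow(img) < 8 || ncol(img) < 8) stop_input("image must be at least 8x8")
  if (method == "identity") return(list(band = img))
  if (nrow(img) %% 2^levels != 0 || ncol(img) %% 2^levels != 0) {
    stop_input("image dimensions must be divisible by 2^levels")
  }
  bands <- list()
  cur <- img
  for (l in seq_len(levels)) {
    st <- haar_dwt2_step(cur)
    bands[[paste0("h", l)]] <- st$LH
    bands[[paste0("v", l)]] <- st$HL
    bands[[paste0("d", l)]] <- st$HH
    cur <- st$LL
  }
  c(stats::setNames(list(cur), paste0("a", levels)), bands)
}

#' Inverse of the default wavelet decomposition
#'
#' Reconstructs the image from the band list produced by
#' `decompose(method = "wavelet")`; used to verify perfect reconstruction.
#'
#' @param bands Named band list from [decompose()].
#' @param levels Number of levels used in the analysis.
#' @return The reconstructed matrix.
#' @export
recompose <- function(bands, levels = 2L) {
  cur <- bands[[paste0("a", levels)]]
  for (l in rev(seq_len(levels))) {
    cur <- haar_idwt2_step(cur, bands[[paste0("h", l)]],
                           bands[[paste0("v", l)]], bands[[paste0("d", l)]])
  }
  cur
}

## ------------------------------------------------- feature aggregation

#' Average feature vectors over GLCM angles
#'
#' Elementwise arithmetic mean of identically named feature vectors, one per
#' angle; the names are preserved.
#'
#' @param features List of named numeric vectors with identical name sets.
#' @return Named numeric vector.
#' @export
average_over_angles <- function(features) {
  if (!length(features)) stop_input("no feature vectors to average")
  nm <- names(features[[1]])
  for (f in features) {
    if (!identical(names(f), nm)) stop_input("feature name sets differ across angles")
  }
  out <- rowMeans(vapply(features, as.numeric, numeric(length(nm))))
  names(out) <- nm
  out
}

#' Bootstrap feature selection by single-feature discriminability
#'
#' For each of `B` bootstrap resamples of the rows, features are ranked by
#' two-sided single-feature AUC, `max(AUC, 1 - AUC)` (a feature separating
#' the classes in the reverse direction is equally useful downstream), and
#' the top `k` recorded. Features appearing in at least `tau * B` of the
#' top-k sets are returned, ordered by selection frequency. Resamples that
#' lose one class are redrawn (at most 100 retries each).
#'
#' @param X Numeric feature matrix or data.frame (rows = samples).
#' @param y Labels, `"benign"`/`"malignant"` (malignant = positive).
#' @param B Number of bootstrap resamples.
#' @param k Number of top features recorded per resample.
#' @param tau Frequency threshold in `[0, 1]` (`tau = 0` keeps every feature
#'   ever ranked top-k).
#' @param seed Integer seed.
#' @return Character vector of selected feature names with the selection
#'   frequency as attribute `"frequency"`.
#' @export
bootstrap_select <- function(X, y, B = 50L, k = 5L, tau = 0.5, seed = 1L) {
  X <- as.matrix(X)
  if (!is_count(B)) stop_input("B must be a positive integer")
  if (!is_count(k) || k > ncol(X)) stop_input("k must lie in 1..n_features")
  pos <- y == "malignant"
  withr::with_seed(seed, {
    hits <- stats::setNames(numeric(ncol(X)), colnames(X))
    for (b in seq_len(B)) {
      for (try in 1:100) {
        idx <- sample.int(nrow(X), replace = TRUE)
        if (length(unique(pos[idx])) == 2) break
        if (try == 100) stop_input("cannot draw a two-class bootstrap resample")
      }
      disc <- apply(X[idx, , drop = FALSE], 2, function(f) {
        a <- rank_auc(f, pos[idx])
        max(a, 1 - a)
      })
      top <- order(disc, decreasing = TRUE)[seq_len(k)]
      hits[top] <- hits[top] + 1
    }
    freq <- hits / B
    sel <- names(sort(freq[freq >= tau & freq > 0], decreasing = TRUE))
    if (tau <= 0) sel <- names(sort(freq[freq > 0], decreasing = TRUE))
    attr(sel, "frequency") <- freq
    sel
  })
}
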