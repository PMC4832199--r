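## Independent brute-force oracles used to validate the implementation.
## These deliberately share no code with the package internals: plain
## double loops and direct summations.

## naive bilinear resize with the same half-pixel grid, one pixel at a time
naive_bilinear <- function(img, out_r, out_c) {
  in_r <- nrow(img); in_c <- ncol(img)
  out <- matrix(0, out_r, out_c)
  for (i in seq_len(out_r)) {
    for (j in seq_len(out_c)) {
      sr <- min(max((i - 0.5) * in_r / out_r - 0.5, 0), in_r - 1)
      sc <- min(max((j - 0.5) * in_c / out_c - 0.5, 0), in_c - 1)
      r0 <- min(floor(sr), in_r - 1); r1 <- min(r0 + 1, in_r - 1)
      c0 <- min(floor(sc), in_c - 1); c1 <- min(c0 + 1, in_c - 1)
      fr <- sr - r0; fc <- sc - c0
      out[i, j] <- img[r0 + 1, c0 + 1] * (1 - fr) * (1 - fc) +
        img[r0 + 1, c1 + 1] * (1 - fr) * fc +
        img[r1 + 1, c0 + 1] * fr * (1 - fc) +
        img[r1 + 1, c1 + 1] * fr * fc
    }
  }
  out
}

## brute-force GLCM by explicit pair enumeration
brute_glcm <- function(img, levels, d, angle, symmetric = TRUE,
                       normalized = TRUE) {
  off <- switch(as.character(angle),
                "0" = c(0, d), "45" = c(-d, d), "90" = c(-d, 0),
                "135" = c(-d, -d))
  P <- matrix(0, levels, levels)
  for (r in seq_len(nrow(img))) {
    for (c in seq_len(ncol(img))) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 >= 1 && r2 <= nrow(img) && c2 >= 1 && c2 <= ncol(img)) {
        P[img[r, c] + 1, img[r2, c2] + 1] <- P[img[r, c] + 1, img[r2, c2] + 1] + 1
      }
    }
  }
  if (symmetric) P <- P + t(P)
  if (normalized && sum(P) > 0) P <- P / sum(P)
  P
}

## brute-force Haralick statistics by direct elementwise summation
brute_haralick <- function(P) {
  L <- nrow(P)
  px <- numeric(L); py <- numeric(L)
  for (i in 1:L) for (j in 1:L) { px[i] <- px[i] + P[i, j]; py[j] <- py[j] + P[i, j] }
  mux <- sum((1:L) * px); muy <- sum((1:L) * py)
  sdx <- sqrt(sum((1:L - mux)^2 * px)); sdy <- sqrt(sum((1:L - muy)^2 * py))
  psum <- numeric(2 * L - 1)  # index k-1 for k = 2..2L
  pdiff <- numeric(L)         # index k+1 for k = 0..L-1
  for (i in 1:L) for (j in 1:L) {
    psum[i + j - 1] <- psum[i + j - 1] + P[i, j]
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + P[i, j]
  }
  H <- function(p) { s <- 0; for (v in p) if (v > 0) s <- s - v * log(v); s }
  energy <- sum(P^2)
  contrast <- sum((0:(L - 1))^2 * pdiff)
  corr <- 0
  if (sdx > 0 && sdy > 0) {
    s <- 0
    for (i in 1:L) for (j in 1:L) s <- s + i * j * P[i, j]
    corr <- (s - mux * muy) / (sdx * sdy)
  }
  variance <- 0
  for (i in 1:L) for (j in 1:L) variance <- variance + (i - mux)^2 * P[i, j]
  idm <- 0
  for (i in 1:L) for (j in 1:L) idm <- idm + P[i, j] / (1 + (i - j)^2)
  ks <- 2:(2 * L)
  sum_average <- sum(ks * psum)
  sum_variance <- sum((ks - sum_average)^2 * psum)
  sum_entropy <- H(psum)
  entropy <- H(P)
  dmean <- sum((0:(L - 1)) * pdiff)
  difference_variance <- sum((0:(L - 1) - dmean)^2 * pdiff)
  difference_entropy <- H(pdiff)
  hx <- H(px); hy <- H(py)
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:L) for (j in 1:L) {
    if (px[i] * py[j] > 0) {
      if (P[i, j] > 0) hxy1 <- hxy1 - P[i, j] * log(px[i] * py[j])
      hxy2 <- hxy2 - px[i] * py[j] * log(px[i] * py[j])
    }
  }
  ic1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  ic2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy))))
  pos <- px > 0 & py > 0
  mcc <- 0
  if (sum(pos) >= 2) {
    n <- sum(pos); Q <- matrix(0, n, n)
    ip <- which(pos)
    for (a in 1:n) for (b in 1:n) {
      for (k in which(py > 0)) {
        Q[a, b] <- Q[a, b] + P[ip[a], k] * P[ip[b], k] / (px[ip[a]] * py[k])
      }
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- sqrt(max(0, ev[2]))
  }
  c(energy = energy, contrast = contrast, correlation = corr,
    variance = variance, inverse_difference_moment = idm,
    sum_average = sum_average, sum_variance = sum_variance,
    sum_entropy = sum_entropy, entropy = entropy,
    difference_variance = difference_variance,
    difference_entropy = difference_entropy,
    info_correlation_1 = ic1, info_correlation_2 = ic2,
    max_correlation_coef = mcc)
}

## O(n^2) all-pairs Mann-Whitney ranklet response of a single window
brute_ranklet_window <- function(vals, treat) {
  t_vals <- vals[treat]; c_vals <- vals[!treat]
  U <- 0
  for (t in t_vals) for (c in c_vals) {
    if (t > c) U <- U + 1 else if (t == c) U <- U + 0.5
  }
  2 * U / (length(t_vals) * length(c_vals)) - 1
}

## all-pairs AUC with half-credit for ties
brute_auc <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  s <- 0
  for (a in sp) for (b in sn) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(sp) * length(sn))
}

## mask solidity = area / convex hull area, via chull on pixel centers
mask_solidity <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) < 3) return(1)
  h <- chull(idx)
  hp <- idx[h, , drop = FALSE]
  n <- nrow(hp)
  area <- abs(sum(hp[, 1] * hp[c(2:n, 1), 2] - hp[c(2:n, 1), 1] * hp[, 2])) / 2
  if (area == 0) return(1)
  min(nrow(idx) / area, 1.5)
}

## central finite-difference gradient of f at x (vector-to-scalar)
fd_grad <- function(f, x, eps = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

## normalized maximal deviation between analytic and numeric gradients
grad_mismatch <- function(analytic, numeric) {
  max(abs(analytic - numeric)) / max(max(abs(numeric)), 1e-8)
}
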