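## Single denoising autoencoder: masking corruption, sigmoid encoder and
## (tied-weight) sigmoid decoder, mean cross-entropy reconstruction loss,
## analytic back-propagated gradients and mini-batch SGD.

#' Training hyperparameters
#'
#' @param learning_rate Positive SGD step size.
#' @param epochs Number of passes over the data (0 = return the initialized
#'   model untouched).
#' @param batch_size Mini-batch size.
#' @param seed Integer seed; fixes initialization, shuffling and corruption.
#' @return An object of class `train_spec`.
#' @export
train_spec <- function(learning_rate = 0.1, epochs = 15L, batch_size = 20L,
                       seed = 1L) {
  if (learning_rate <= 0) stop_input("learning_rate must be positive")
  if (!is.numeric(epochs) || epochs < 0 || epochs != round(epochs)) {
    stop_input("epochs must be a nonnegative integer")
  }
  if (!is_count(batch_size)) stop_input("batch_size must be a positive integer")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "train_spec")
}

## Standard sigmoid initialization: W ~ U(+-4 sqrt(6/(fan_in + fan_out))),
## zero biases.
new_dae_layer <- function(d_in, d_hidden, corruption_level = 0.3, tied = TRUE) {
  lim <- 4 * sqrt(6 / (d_in + d_hidden))
  structure(
    list(W = matrix(stats::runif(d_hidden * d_in, -lim, lim), d_hidden, d_in),
         b_enc = numeric(d_hidden),
         b_dec = numeric(d_in),
         corruption_level = corruption_level,
         tied = tied),
    class = "dae_layer")
}

#' @export
print.dae_layer <- function(x, ...) {
  cat(sprintf("dae_layer %d -> %d (corruption %.2f, %s weights)\n",
              ncol(x$W), nrow(x$W), x$corruption_level,
              if (x$tied) "tied" else "untied"))
  invisible(x)
}

#' Masking corruption
#'
#' Sets exactly `floor(level * d)` distinct coordinates, chosen uniformly
#' without replacement from the current RNG stream, to zero; all other
#' coordinates are untouched. The exact (rather than Bernoulli) count makes
#' the corrupted fraction deterministic.
#'
#' @param x Numeric vector (columns of a matrix are corrupted
#'   independently).
#' @param level Fraction in `[0, 1]` of coordinates to mask.
#' @return Corrupted copy of `x`.
#' @export
corrupt <- function(x, level) {
  if (!is_prob(level)) stop_input("corruption level must lie in [0, 1]")
  if (is.matrix(x)) {
    k <- floor(level * nrow(x))
    if (k == 0) return(x)
    for (j in seq_len(ncol(x))) {
      x[sample.int(nrow(x), k), j] <- 0
    }
    return(x)
  }
  k <- floor(level * length(x))
  if (k > 0) x[sample.int(length(x), k)] <- 0
  x
}

#' Encoder forward pass
#'
#' `h = sigmoid(W x + b_enc)`; accepts a vector or a d x n matrix of
#' column samples.
#'
#' @param layer A `dae_layer`.
#' @param x Input vector/matrix with `d_in` rows.
#' @return Hidden activation(s) in (0, 1).
#' @export
dae_encode <- function(layer, x) {
  x <- as.matrix(x)
  if (nrow(x) != ncol(layer$W)) stop_input("input dimension mismatch")
  h <- sigmoid(layer$W %*% x + layer$b_enc)
  if (ncol(h) == 1) drop(h) else h
}

#' Decoder forward pass
#'
#' `z = sigmoid(W' h + b_dec)` with tied weights (the decoder reuses the
#' transposed encoder matrix).
#'
#' @param layer A `dae_layer`.
#' @param h Hidden vector/matrix with `d_hidden` rows.
#' @return Reconstruction(s) in (0, 1).
#' @export
dae_reconstruct <- function(layer, h) {
  h <- as.matrix(h)
  if (nrow(h) != nrow(layer$W)) stop_input("hidden dimension mismatch")
  z <- sigmoid(crossprod(layer$W, h) + layer$b_dec)
  if (ncol(z) == 1) drop(z) else z
}

#' Mean cross-entropy reconstruction loss
#'
#' `-(1/d) sum(x log z + (1 - x) log(1 - z))` with `z` clipped to
#' `[1e-7, 1 - 1e-7]`, so the loss is always finite.
#'
#' @param x Clean input in `[0, 1]^d`.
#' @param z Reconstruction in `[0, 1]^d` (matrix input: mean over columns).
#' @return Nonnegative scalar.
#' @export
dae_loss <- function(x, z) {
  eps <- 1e-7
  z <- pmin(pmax(z, eps), 1 - eps)
  -mean(x * log(z) + (1 - x) * log(1 - z))
}

#' Analytic gradients of the reconstruction loss
#'
#' Back-propagates `dae_loss(x_clean, dae_reconstruct(layer,
#' dae_encode(layer, x_corrupt)))` through the tied-weight architecture.
#' Matrix inputs (column samples) return gradients averaged over the batch.
#'
#' @param layer A `dae_layer`.
#' @param x_clean Clean target vector/matrix.
#' @param x_corrupt Corrupted input vector/matrix.
#' @return List with `W`, `b_enc`, `b_dec` gradient arrays and the batch
#'   `loss`.
#' @export
dae_grad <- function(layer, x_clean, x_corrupt) {
  X <- as.matrix(x_clean); Xc <- as.matrix(x_corrupt)
  if (!all(dim(X) == dim(Xc))) stop_input("clean/corrupt shapes differ")
  d <- nrow(X); B <- ncol(X)
  H <- sigmoid(layer$W %*% Xc + layer$b_enc)
  Z <- sigmoid(crossprod(layer$W, H) + layer$b_dec)
  ## cross-entropy + sigmoid: d loss / d z_pre = (z - x) / d
  Ddec <- (Z - X) / d
  Denc <- (layer$W %*% Ddec) * H * (1 - H)
  list(W = (H %*% t(Ddec) + Denc %*% t(Xc)) / B,
       b_enc = rowSums(Denc) / B,
       b_dec = rowSums(Ddec) / B,
       loss = dae_loss(X, Z))
}

#' Train one denoising autoencoder layer by mini-batch SGD
#'
#' Initializes a tied-weight layer, then for each epoch shuffles the
#' samples, corrupts each mini-batch with masking noise and takes one SGD
#' step per batch. All randomness (initialization, shuffling, corruption)
#' derives from `spec$seed`, so a fixed seed gives a bitwise-identical
#' trajectory.
#'
#' @param data d x n matrix of training vectors in `[0, 1]` (one column per
#'   sample), or a list of equal-length vectors.
#' @param d_hidden Hidden-layer width.
#' @param spec A [train_spec()].
#' @param level Masking-corruption fraction.
#' @return A `dae_layer` with attribute `"curve"` holding the mean loss of
#'   each epoch.
#' @export
train_dae <- function(data, d_hidden, spec = train_spec(), level = 0.3) {
  if (is.list(data) && !is.matrix(data)) data <- do.call(cbind, data)
  data <- as.matrix(data)
  if (ncol(data) == 0) stop_input("empty training data")
  if (!is_count(d_hidden)) stop_input("d_hidden must be a positive integer")
  withr::with_seed(spec$seed, {
    layer <- new_dae_layer(nrow(data), d_hidden, corruption_level = level)
    curve <- numeric(spec$epochs)
    n <- ncol(data)
    for (ep in seq_len(spec$epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1, n, by = spec$batch_size)) {
        idx <- ord[start:min(start + spec$batch_size - 1, n)]
        X <- data[, idx, drop = FALSE]
        Xc <- corrupt(X, level)
        g <- dae_grad(layer, X, Xc)
        layer$W <- layer$W - spec$learning_rate * g$W
        layer$b_enc <- layer$b_enc - spec$learning_rate * g$b_enc
        layer$b_dec <- layer$b_dec - spec$learning_rate * g$b_dec
        losses <- c(losses, g$loss)
      }
      curve[ep] <- mean(losses)
    }
    attr(layer, "curve") <- curve
    layer
  })
}
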