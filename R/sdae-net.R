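## Stacked denoising autoencoder classifier. Greedy layer-wise pretraining
## builds the 784 -> 200 -> 100 encoder stack from unlabeled patches; the
## supervised network adds three auxiliary geometry inputs at the input
## layer (wired into hidden layer 1 through a zero-initialized matrix, so
## fine-tuning starts exactly at the pretrained solution) and a two-class
## softmax head, then fine-tunes everything by back-propagation.

#' Greedy layer-wise pretraining of the encoder stack
#'
#' Layer 1 is a denoising autoencoder trained on the 784-dimensional patch
#' vectors; layer 2 is trained on the clean layer-1 hidden codes. Both use
#' masking corruption and mini-batch SGD.
#'
#' @param samples List of `roi_sample` objects (labels are ignored).
#' @param spec A [train_spec()]; `spec$seed` drives both layers.
#' @param hidden_sizes Widths of the hidden layers, default `c(200, 100)`.
#' @param corruption Masking fraction per layer (recycled).
#' @return List of `dae_layer` objects, each carrying its training curve as
#'   attribute `"curve"`.
#' @export
sdae_pretrain <- function(samples, spec = train_spec(),
                          hidden_sizes = c(200L, 100L), corruption = 0.3) {
  if (!length(samples)) stop_input("no samples for pretraining")
  X <- patch_vectors(samples)
  corruption <- rep(corruption, length.out = length(hidden_sizes))
  layers <- vector("list", length(hidden_sizes))
  for (l in seq_along(hidden_sizes)) {
    lspec <- train_spec(spec$learning_rate, spec$epochs, spec$batch_size,
                        seed = spec$seed + l - 1L)
    layers[[l]] <- train_dae(X, hidden_sizes[l], lspec, corruption[l])
    X <- dae_encode(layers[[l]], X)
  }
  layers
}

labels_to_onehot <- function(labels) {
  y <- matrix(0, 2, length(labels))
  y[1, labels == "benign"] <- 1
  y[2, labels == "malignant"] <- 1
  if (any(colSums(y) == 0)) stop_input("labels must be benign/malignant")
  y
}

softmax_cols <- function(S) {
  S <- sweep(S, 2, apply(S, 2, max))
  E <- exp(S)
  sweep(E, 2, colSums(E), "/")
}

## Forward pass of the supervised network on column samples.
## P: d_pix x n pixels, U: 3 x n standardized auxiliaries.
sdae_forward <- function(par, P, U) {
  Z1 <- sigmoid(par$W1 %*% P + par$A %*% U + par$b1)
  Z2 <- sigmoid(par$W2 %*% Z1 + par$b2)
  Prob <- softmax_cols(par$W3 %*% Z2 + par$b3)
  list(Z1 = Z1, Z2 = Z2, Prob = Prob)
}

## Mean cross-entropy of the softmax head over the batch.
sdae_ce_loss <- function(Prob, Y) {
  eps <- 1e-12
  -mean(colSums(Y * log(pmax(Prob, eps))))
}

## Analytic gradients of the full supervised network, averaged over the
## batch. Kept shape-generic so small networks can be checked against
## finite differences.
sdae_grad <- function(par, P, U, Y) {
  B <- ncol(P)
  fw <- sdae_forward(par, P, U)
  Ds <- (fw$Prob - Y) / B
  D2 <- (crossprod(par$W3, Ds)) * fw$Z2 * (1 - fw$Z2)
  D1 <- (crossprod(par$W2, D2)) * fw$Z1 * (1 - fw$Z1)
  list(W3 = Ds %*% t(fw$Z2), b3 = rowSums(Ds),
       W2 = D2 %*% t(fw$Z1), b2 = rowSums(D2),
       W1 = D1 %*% t(P), A = D1 %*% t(U), b1 = rowSums(D1),
       loss = sdae_ce_loss(fw$Prob, Y))
}

#' Fine-tune the supervised SDAE classifier
#'
#' Builds the supervised network from the pretrained encoder stack: pixel
#' weights and biases are the pretrained encoder parameters, the auxiliary
#' input matrix starts at zero (so the initial forward pass equals the
#' pretrained encoding), and the softmax head starts with small seeded
#' uniform noise. The whole network is then optimized by mini-batch SGD on
#' the softmax cross-entropy. The auxiliary standardizer is fitted on the
#' training samples only.
#'
#' @param pretrained List of `dae_layer` objects from [sdae_pretrain()].
#' @param train List of labelled `roi_sample` objects containing both
#'   classes.
#' @param spec A [train_spec()]; defaults to
#'   `train_spec(0.05, 100, 20, seed)`.
#' @return An object of class `sdae_model` with attribute `"curve"`.
#' @export
sdae_finetune <- function(pretrained, train,
                          spec = train_spec(learning_rate = 0.05,
                                            epochs = 100L, batch_size = 20L)) {
  labels <- vapply(train, function(s) s$label, character(1))
  if (length(unique(labels)) < 2) {
    stop_input("training set must contain both classes")
  }
  std <- fit_aux_standardizer(train)
  P <- patch_vectors(train)
  U <- vapply(train, function(s) (aux_of(s) - std$mean) / std$sd, numeric(3))
  Y <- labels_to_onehot(labels)
  n <- ncol(P)
  withr::with_seed(spec$seed, {
    d2 <- nrow(pretrained[[2]]$W)
    par <- list(W1 = pretrained[[1]]$W, b1 = pretrained[[1]]$b_enc,
                A = matrix(0, nrow(pretrained[[1]]$W), 3),
                W2 = pretrained[[2]]$W, b2 = pretrained[[2]]$b_enc,
                W3 = matrix(stats::runif(2 * d2, -0.01, 0.01), 2, d2),
                b3 = numeric(2))
    curve <- numeric(spec$epochs)
    for (ep in seq_len(spec$epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1, n, by = spec$batch_size)) {
        idx <- ord[start:min(start + spec$batch_size - 1, n)]
        g <- sdae_grad(par, P[, idx, drop = FALSE], U[, idx, drop = FALSE],
                       Y[, idx, drop = FALSE])
        for (nm in c("W1", "A", "b1", "W2", "b2", "W3", "b3")) {
          par[[nm]] <- par[[nm]] - spec$learning_rate * g[[nm]]
        }
        losses <- c(losses, g$loss)
      }
      curve[ep] <- mean(losses)
    }
    structure(
      list(layer_sizes = c(ncol(par$W1), nrow(par$W1), nrow(par$W2)),
           par = par, aux_standardizer = std, classes = c("benign", "malignant")),
      class = "sdae_model", curve = curve)
  })
}

#' @export
print.sdae_model <- function(x, ...) {
  cat("sdae_model:", paste(x$layer_sizes, collapse = " -> "),
      "-> softmax(2), 3 auxiliary inputs\n")
  invisible(x)
}

#' Predict class probabilities for ROI samples
#'
#' Deterministic forward pass through the fitted network. The hard label is
#' the argmax of the softmax; an exact tie at 0.5 is resolved to benign.
#'
#' @param model A fitted `sdae_model`.
#' @param samples A single `roi_sample` or a list of them.
#' @return A data.frame with columns `case_id`, `slice_index`, `p_benign`,
#'   `p_malignant`, `hard_label`.
#' @export
sdae_predict <- function(model, samples) {
  if (!inherits(model, "sdae_model")) stop_input("model is not a fitted sdae_model")
  if (inherits(samples, "roi_sample")) samples <- list(samples)
  std <- model$aux_standardizer
  P <- patch_vectors(samples)
  U <- vapply(samples, function(s) (aux_of(s) - std$mean) / std$sd, numeric(3))
  Prob <- sdae_forward(model$par, P, as.matrix(U))$Prob
  data.frame(
    case_id = vapply(samples, function(s) s$case_id, character(1)),
    slice_index = vapply(samples, function(s) s$slice_index, integer(1)),
    p_benign = Prob[1, ],
    p_malignant = Prob[2, ],
    hard_label = ifelse(Prob[2, ] > Prob[1, ], "malignant", "benign"),
    stringsAsFactors = FALSE)
}

#' Reconstruct hidden-layer patterns as 28x28 images
#'
#' Layer 1 patterns are the encoder weight rows reshaped to 28x28. Layer 2
#' patterns are built as the weighted sums of all first-layer patterns with
#' the second-layer weights as coefficients, taking every first-layer neuron
#' as active. Every pattern is min-max normalized for presentation.
#'
#' @param layers List of `dae_layer` objects (from [sdae_pretrain()]) or an
#'   `sdae_model`.
#' @param layer 1 or 2.
#' @return List of 28x28 matrices in `[0, 1]`, one per hidden unit.
#' @export
layer_patterns <- function(layers, layer) {
  if (inherits(layers, "sdae_model")) {
    W1 <- layers$par$W1; W2 <- layers$par$W2
  } else {
    W1 <- layers[[1]]$W
    W2 <- if (length(layers) >= 2) layers[[2]]$W else NULL
  }
  if (!layer %in% c(1, 2)) stop_input("layer must be 1 or 2")
  if (layer == 1) {
    lapply(seq_len(nrow(W1)), function(j) {
      minmax01(matrix(W1[j, ], PATCH_SIDE, PATCH_SIDE, byrow = TRUE))
    })
  } else {
    if (is.null(W2)) stop_input("no second layer available")
    lapply(seq_len(nrow(W2)), function(j) {
      acc <- W2[j, ] %*% W1       # weighted sum of raw first-layer patterns
      minmax01(matrix(acc, PATCH_SIDE, PATCH_SIDE, byrow = TRUE))
    })
  }
}
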