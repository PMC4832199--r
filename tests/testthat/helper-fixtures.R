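## Small shared fixtures, built in code at test time.

tiny_us_cases <- function(n_per_class = 3, seed = 11, size = 32) {
  generate_us_dataset(synth_config("us", n_per_class, n_per_class,
                                   image_size = size, seed = seed))
}

tiny_ct_cases <- function(n_per_class = 3, seed = 12, size = 48,
                          slices = c(3L, 5L)) {
  generate_ct_dataset(synth_config("ct", n_per_class, n_per_class,
                                   image_size = size,
                                   slices_per_case_range = slices,
                                   seed = seed))
}

## patch samples whose class is trivially linearly separable: benign
## patches are bright in the left half, malignant in the right half
separable_samples <- function(n_per_class = 50, seed = 5) {
  withr::with_seed(seed, {
    mk <- function(label, i) {
      p <- matrix(runif(28 * 28, 0, 0.2), 28, 28)
      if (label == "benign") p[, 1:14] <- p[, 1:14] + 0.7
      else p[, 15:28] <- p[, 15:28] + 0.7
      s <- to_patch(p, label = label, case_id = sprintf("%s%03d", label, i))
      s
    }
    c(lapply(seq_len(n_per_class), function(i) mk("benign", i)),
      lapply(seq_len(n_per_class), function(i) mk("malignant", i)))
  })
}

random_roi_samples <- function(n = 20, seed = 3) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      nr <- sample(20:60, 1); nc <- sample(20:60, 1)
      to_patch(matrix(runif(nr * nc), nr, nc),
               label = sample(c("benign", "malignant"), 1),
               case_id = sprintf("r%03d", i))
    })
  })
}
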