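test_that("GLCM matches hand-worked small examples", {
  spec <- glcm_spec(levels = 4)
  P <- glcm(matrix(2, 5, 5), spec, 1, 0)
  expect_equal(P[3, 3], 1) # constant image: all mass in one cell
  expect_equal(sum(P), 1)
  ## [[0,1],[0,1]] at distance 1, angle 0: only (0,1) pairs, symmetrized
  P2 <- glcm(matrix(c(0, 0, 1, 1), 2, 2), glcm_spec(levels = 2), 1, 0)
  expect_equal(P2, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  expect_error(glcm(matrix(5, 2, 2), glcm_spec(levels = 4)), "levels")
})

test_that("GLCM equals brute-force pair enumeration on random 8x8 images", {
  withr::with_seed(40, {
    for (i in 1:50) {
      img <- matrix(sample(0:7, 64, replace = TRUE), 8, 8)
      d <- sample(1:2, 1); ang <- sample(c(0, 45, 90, 135), 1)
      sym <- i %% 2 == 0
      spec <- glcm_spec(levels = 8, distances = d, angles = ang,
                        symmetric = sym)
      expect_identical(glcm(img, spec, d, ang),
                       brute_glcm(img, 8, d, ang, symmetric = sym))
    }
  })
  ## normalization property
  withr::with_seed(41, {
    img <- matrix(sample(0:15, 400, replace = TRUE), 20, 20)
    expect_equal(sum(glcm(img, glcm_spec(levels = 16))), 1, tolerance = 1e-12)
  })
})

test_that("Haralick features have the degenerate and checkerboard closed forms", {
  P <- glcm(matrix(3, 6, 6), glcm_spec(levels = 8), 1, 0)
  f <- haralick(P)
  expect_equal(unname(f["energy"]), 1)
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["entropy"]), 0)
  ## checkerboard with levels {0, q}: every horizontal pair differs by q
  q <- 5
  img <- q * outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  fc <- haralick(glcm(img, glcm_spec(levels = 8), 1, 0))
  expect_equal(unname(fc["contrast"]), q^2)
  expect_error(haralick(matrix(1, 4, 4)), "normalized")
})

test_that("all 14 Haralick features match the direct-summation oracle", {
  withr::with_seed(42, {
    for (i in 1:20) {
      L <- sample(4:8, 1)
      img <- matrix(sample(0:(L - 1), 100, replace = TRUE), 10, 10)
      P <- glcm(img, glcm_spec(levels = L), 1, sample(c(0, 45, 90, 135), 1))
      got <- haralick(P)
      want <- brute_haralick(P)
      expect_equal(unname(got), unname(want), tolerance = 1e-10)
      expect_identical(names(got), names(want))
    }
  })
  ## the 12-feature subset drops exactly two statistics
  f12 <- haralick(glcm(matrix(c(0, 1, 2, 3), 2, 2), glcm_spec(levels = 4)),
                  subset = sdaecadx:::haralick_names_12)
  expect_length(f12, 12)
})

test_that("Haralick features of a symmetric GLCM survive 180-degree rotation", {
  withr::with_seed(43, {
    img <- matrix(sample(0:7, 144, replace = TRUE), 12, 12)
    rot <- img[12:1, 12:1]
    for (ang in c(0, 45, 90, 135)) {
      spec <- glcm_spec(levels = 8, angles = ang)
      expect_equal(haralick(glcm(img, spec, 1, ang)),
                   haralick(glcm(rot, spec, 1, ang)), tolerance = 1e-12)
    }
  })
})

test_that("ranklet responses hit the extremes and honour ties", {
  ## treatment half strictly brighter than control half: response +1
  img <- cbind(matrix(0, 4, 2), matrix(1, 4, 2))
  r <- ranklet_transform(img, ranklet_spec(4L, "vertical"))[[1]]
  expect_equal(as.vector(r), 1)
  ## flipped: -1
  r2 <- ranklet_transform(img[, 4:1], ranklet_spec(4L, "vertical"))[[1]]
  expect_equal(as.vector(r2), -1)
  ## constant window: all ties, response 0
  r3 <- ranklet_transform(matrix(0.3, 4, 4), ranklet_spec(4L))[[1]]
  expect_equal(as.vector(r3), 0)
  expect_error(ranklet_spec(5L), "even")
  expect_error(ranklet_transform(matrix(0, 3, 3), ranklet_spec(4L)), "exceeds")
})

test_that("ranklet responses equal the all-pairs counting oracle on 6x6 windows", {
  withr::with_seed(44, {
    for (i in 1:10) {
      img <- matrix(sample(0:4, 36, replace = TRUE), 6, 6) # ties guaranteed
      for (orient in c("vertical", "horizontal", "diagonal")) {
        got <- ranklet_transform(img, ranklet_spec(6L, orient))[[1]]
        treat <- as.vector(sdaecadx:::ranklet_split(6L, orient))
        expect_equal(as.vector(got),
                     brute_ranklet_window(as.vector(img), treat),
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("ranklet responses are exactly invariant to monotone transforms", {
  withr::with_seed(45, {
    transforms <- list(function(x) x^3, function(x) exp(2 * x),
                       function(x) 5 * x + 7)
    for (i in 1:10) {
      img <- matrix(runif(100), 10, 10)
      base <- ranklet_transform(img, ranklet_spec(4L))
      for (tf in transforms) {
        expect_identical(ranklet_transform(tf(img), ranklet_spec(4L)), base)
      }
    }
  })
})

test_that("sub-band decomposition returns the advertised bands and inverts exactly", {
  img <- matrix(runif(28 * 28), 28)
  one <- decompose(img, "identity")
  expect_length(one, 1)
  expect_identical(one[[1]], img)
  bands <- decompose(img, "wavelet")
  expect_length(bands, 7) # 1 approximation + 2 x 3 detail bands
  expect_identical(sort(names(bands)),
                   sort(c("a2", "h1", "v1", "d1", "h2", "v2", "d2")))
  expect_lt(max(abs(recompose(bands) - img)), 1e-8)
  ## plugin hook
  plug <- decompose(img, function(x) list(neg = -x))
  expect_identical(plug$neg, -img)
  expect_error(decompose(matrix(0, 4, 4)), "8x8")
  expect_error(decompose(matrix(0, 30, 30), "wavelet"), "divisible")
})

test_that("angle averaging is the elementwise mean with names preserved", {
  a <- c(x = 1, y = 10); b <- c(x = 3, y = 20)
  expect_equal(average_over_angles(list(a)), a)
  expect_equal(average_over_angles(list(a, b)), c(x = 2, y = 15))
  withr::with_seed(46, {
    per_angle <- lapply(1:4, function(i) {
      setNames(runif(14), sdaecadx:::haralick_names)
    })
    manual <- setNames(numeric(14), sdaecadx:::haralick_names)
    for (f in per_angle) manual <- manual + f / 4
    expect_equal(average_over_angles(per_angle), manual, tolerance = 1e-12)
  })
  expect_error(average_over_angles(list(a, c(x = 1, z = 2))), "name sets")
})

test_that("bootstrap selection finds a perfectly separating feature", {
  withr::with_seed(47, {
    n <- 60
    y <- rep(c("benign", "malignant"), each = n / 2)
    X <- matrix(rnorm(n * 8), n, 8,
                dimnames = list(NULL, paste0("f", 1:8)))
    X[, "f3"] <- ifelse(y == "malignant", 1, 0) + rnorm(n, 0, 0.01)
  })
  sel <- bootstrap_select(X, y, B = 50, k = 2, tau = 0.9, seed = 2)
  expect_true("f3" %in% sel)
  expect_equal(unname(attr(sel, "frequency")["f3"]), 1.0)
  ## threshold extremes
  all_seen <- bootstrap_select(X, y, B = 10, k = 3, tau = 0, seed = 2)
  expect_true(length(all_seen) >= 3)
  expect_length(bootstrap_select(X, y, B = 10, k = 3, tau = 1.01, seed = 2), 0)
  ## determinism
  expect_identical(bootstrap_select(X, y, B = 20, k = 2, tau = 0.5, seed = 5),
                   bootstrap_select(X, y, B = 20, k = 2, tau = 0.5, seed = 5))
})
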