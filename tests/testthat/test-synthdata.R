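test_that("US generator honours configured class counts and labelling", {
  cfg <- synth_config("us", n_benign = 275, n_malignant = 245,
                      image_size = 32, seed = 2)
  cases <- generate_us_dataset(cfg)
  expect_length(cases, 520)
  labels <- vapply(cases, function(x) x$label, character(1))
  expect_equal(sum(labels == "benign"), 275)
  expect_equal(sum(labels == "malignant"), 245)
  expect_true(all(vapply(cases, function(x) length(x$images) == 1, logical(1))))
  ## lesion darker than surround, mask nonempty
  cs <- cases[[1]]
  expect_gt(sum(cs$masks[[1]]), 0)
  expect_lt(mean(cs$images[[1]][cs$masks[[1]] > 0]),
            mean(cs$images[[1]][cs$masks[[1]] == 0]))
})

test_that("generators are byte-deterministic under a fixed seed", {
  cfg <- synth_config("us", 4, 4, image_size = 32, seed = 7)
  expect_identical(generate_us_dataset(cfg), generate_us_dataset(cfg))
  cfg2 <- synth_config("ct", 2, 2, image_size = 32,
                       slices_per_case_range = c(2L, 4L), seed = 7)
  expect_identical(generate_ct_dataset(cfg2), generate_ct_dataset(cfg2))
})

test_that("configuration errors are rejected", {
  expect_error(synth_config("us", 0, 5), "positive integers")
  expect_error(synth_config("us", 5, 5, image_size = 4), "image_size")
  expect_error(synth_config("ct", 5, 5, slice_thickness = 11), "0, 10")
  expect_error(synth_config("ct", 5, 5, slice_thickness = 0), "0, 10")
  expect_error(synth_config("ct", 5, 5, slices_per_case_range = c(4, 2)),
               "interval")
  expect_error(generate_us_dataset(synth_config("ct", 2, 2)), "modality")
})

test_that("boundary irregularity drives mask solidity apart between classes", {
  ## default effect sizes: malignant masks are less solid (spiculated)
  cfg <- synth_config("us", 200, 200, image_size = 48, seed = 21)
  sol <- vapply(generate_us_dataset(cfg),
                function(x) mask_solidity(x$masks[[1]]), numeric(1))
  lab <- rep(c("benign", "malignant"), each = 200)
  expect_lt(t.test(sol[lab == "benign"], sol[lab == "malignant"])$p.value, 0.01)
  expect_gt(mean(sol[lab == "benign"]), mean(sol[lab == "malignant"]))
})

test_that("equal effect parameters leave solidity distributions equal", {
  pvals <- vapply(1:5, function(s) {
    cfg <- synth_config("us", 100, 100, image_size = 48, seed = 100 + s,
                        boundary_irregularity = c(benign = 0, malignant = 0),
                        texture_contrast = c(benign = 0.1, malignant = 0.1))
    cases <- generate_us_dataset(cfg)
    sol <- vapply(cases, function(x) mask_solidity(x$masks[[1]]), numeric(1))
    lab <- rep(c("benign", "malignant"), each = 100)
    t.test(sol[lab == "benign"], sol[lab == "malignant"])$p.value
  }, numeric(1))
  expect_gte(sum(pvals > 0.01), 4) # equality not rejected in ~alpha proportion
})

test_that("CT cases have the configured slice counts and connected masks", {
  cfg <- synth_config("ct", 3, 3, image_size = 48,
                      slices_per_case_range = c(2L, 6L), seed = 5)
  cases <- generate_ct_dataset(cfg)
  ks <- vapply(cases, function(x) length(x$images), integer(1))
  expect_true(all(ks >= 2 & ks <= 6))
  for (cs in cases) {
    expect_equal(length(cs$images), length(cs$masks))
    expect_true(all(vapply(cs$masks, sum, numeric(1)) > 0))
  }
  ## degenerate range: every case single-slice
  cfg1 <- synth_config("ct", 3, 3, image_size = 48,
                       slices_per_case_range = c(1L, 1L), seed = 5)
  expect_true(all(vapply(generate_ct_dataset(cfg1),
                         function(x) length(x$images), integer(1)) == 1))
})

test_that("spherical nodule cross-sections match analytic circle areas", {
  sp <- ct_nodule_case(c(5, 5, 5), n_slices = 9, slice_thickness = 1,
                       pixel_spacing = 0.5, image_size = 64)
  areas_px <- vapply(sp$masks, sum, numeric(1))
  expect_equal(areas_px, rev(areas_px)) # symmetric about the middle slice
  expect_equal(which.max(areas_px), 5)  # maximal at the middle
  ## r(z) = sqrt(R^2 - z^2); allow <= 2 boundary-pixel rows of error
  for (j in 1:9) {
    z <- j - 5
    r_px <- sqrt(25 - z^2) / 0.5
    analytic_px <- pi * r_px^2
    boundary <- 2 * pi * r_px * 2
    expect_lt(abs(areas_px[j] - analytic_px), boundary)
  }
})

test_that("manifest write/read round-trips the case structure", {
  dir <- withr::local_tempdir()
  cases <- tiny_ct_cases(2, seed = 9, slices = c(3L, 3L))
  path <- write_manifest(cases, dir)
  m <- read.csv(path)
  expect_equal(nrow(m), 4 * 3) # 4 cases x 3 slices
  expect_true(all(m$label %in% c("benign", "malignant")))
  back <- read_manifest(path)
  expect_equal(length(back), length(cases))
  for (i in seq_along(cases)) {
    expect_equal(back[[i]]$case_id, cases[[i]]$case_id)
    expect_equal(back[[i]]$label, cases[[i]]$label)
    expect_equal(back[[i]]$images, cases[[i]]$images, tolerance = 1 / 254)
    expect_identical(lapply(back[[i]]$masks, function(m) m > 0),
                     lapply(cases[[i]]$masks, function(m) m > 0))
  }
})

test_that("identical configs produce identical files on disk", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- synth_config("us", 2, 2, image_size = 32, seed = 13)
  p1 <- write_manifest(generate_us_dataset(cfg), d1)
  p2 <- write_manifest(generate_us_dataset(cfg), d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  pngs <- f1[grepl("png$", f1)]
  expect_identical(lapply(file.path(d1, pngs), function(p) readBin(p, "raw", 1e6)),
                   lapply(file.path(d2, pngs), function(p) readBin(p, "raw", 1e6)))
})
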