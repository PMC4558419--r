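test_that("ground truth is consistent with the rendered dot mask", {
  spec <- synthetic_spec(group = "BNH", nuclei_per_image = 10,
                         dots_per_nucleus_mean = 3,
                         arrangement = "disorganized", noise_sd = 0, seed = 7)
  res <- generate_image(spec)
  expect_equal(nrow(res$truth$object_table),
               flood_fill_count(res$truth$dot_mask))
  # every dot pixel has exactly one compartment; object rows carry one tag
  expect_true(all(res$truth$object_table$compartment %in%
                    c("epithelium", "stroma")))
  # epithelial dots reference existing nuclei
  nid <- res$truth$object_table$nucleus_id
  expect_true(all(is.na(nid) | nid %in% seq_len(max(res$truth$nucleus_mask))))
})

test_that("zero dot rate produces an empty object table and mask", {
  spec <- synthetic_spec(dots_per_nucleus_mean = 0, stromal_dots_mean = 0,
                         seed = 3)
  res <- generate_image(spec)
  expect_equal(nrow(res$truth$object_table), 0)
  expect_false(any(res$truth$dot_mask))
})

test_that("identical spec and seed give bit-identical output", {
  spec <- synthetic_spec(seed = 11)
  a <- generate_image(spec)
  b <- generate_image(spec)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$object_table, b$truth$object_table)
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(generate_image(synthetic_spec(seed = 5)))
  expect_identical(runif(1), before)
})

test_that("impossible nucleus packing fails explicitly", {
  spec <- synthetic_spec(nuclei_per_image = 30, nucleus_radius_px = 20,
                         image_size = 64L, arrangement = "disorganized",
                         seed = 1)
  expect_error(generate_image(spec), "packing limit")
})

test_that("cohorts have the stated size, labels and derived seeds", {
  specs <- null_group_specs()
  coh <- generate_cohort(specs, images_per_group = 5, seed = 42)
  expect_length(coh, 30)
  expect_equal(as.vector(table(vapply(coh, `[[`, "", "group"))[group_labels()]),
               rep(5L, 6))
  # determinism: same master seed, same per-image object counts
  coh2 <- generate_cohort(specs, images_per_group = 5, seed = 42)
  n1 <- vapply(coh, function(x) nrow(x$truth$object_table), 1L)
  n2 <- vapply(coh2, function(x) nrow(x$truth$object_table), 1L)
  expect_identical(n1, n2)
  # different master seed changes the rendered masks
  coh3 <- generate_cohort(specs, images_per_group = 5, seed = 43)
  s1 <- sum(vapply(coh, function(x) sum(x$truth$dot_mask), 1L))
  s3 <- sum(vapply(coh3, function(x) sum(x$truth$dot_mask), 1L))
  expect_false(s1 == s3)
})

test_that("a missing group in the cohort map is reported by name", {
  specs <- null_group_specs()
  specs$G3 <- NULL
  expect_error(generate_cohort(specs, 2, seed = 1), "G3")
})

test_that("increasing the aspect-ratio knob increases realised aspect ratios", {
  mean_aspect <- function(target) {
    v <- c()
    for (s in 1:12) {
      sp <- synthetic_spec(aspect_ratio_mean = target,
                           arrangement = "disorganized", nuclei_per_image = 8,
                           seed = 500 + s)
      v <- c(v, generate_image(sp)$truth$object_table$true_aspect_ratio)
    }
    v
  }
  a1 <- mean_aspect(1.0); a2 <- mean_aspect(1.3); a3 <- mean_aspect(1.6)
  expect_gt(length(a1), 100)
  expect_lt(mean(a1), mean(a2))
  expect_lt(mean(a2), mean(a3))
})

test_that("composites are exact tile grids with merged ground truth", {
  spec <- synthetic_spec(group = "AAH", kind = "composite", image_size = 96L,
                         nuclei_per_image = 4, nucleus_radius_px = 12,
                         seed = 3)
  res <- generate_image(spec)
  expect_equal(dim(res$image$pixels)[1:2], c(4L, 6L) * 96L)
  expect_equal(res$image$kind, "composite")
  expect_equal(nrow(res$truth$object_table),
               flood_fill_count(res$truth$dot_mask))
  # centroids in global coordinates land on dot pixels
  tab <- res$truth$object_table
  idx <- cbind(round(tab$centroid_r) + 1, round(tab$centroid_c) + 1)
  near <- vapply(seq_len(nrow(idx)), function(i) {
    r <- idx[i, 1]; c <- idx[i, 2]
    any(res$truth$dot_mask[max(1, r - 3):min(nrow(res$truth$dot_mask), r + 3),
                           max(1, c - 3):min(ncol(res$truth$dot_mask), c + 3)])
  }, TRUE)
  expect_true(all(near))
})

test_that("spec validation enforces the stated parameter ranges", {
  expect_error(synthetic_spec(ruggedness_amplitude = 0.7), "amplitude")
  expect_error(synthetic_spec(aspect_ratio_mean = 0.8), "aspect")
  expect_error(synthetic_spec(image_size = 32), "image_size")
  expect_error(synthetic_spec(group = "G9"), "group")
})

test_that("the compiled dot rasterizer matches the reference formula", {
  set.seed(61)
  for (i in 1:20) {
    d <- list(row = runif(1, 20, 44), col = runif(1, 20, 44),
              radius = runif(1, 2, 8), aspect = runif(1, 1, 2),
              amplitude = runif(1, 0, 0.4), harmonics = sample(2:16, 1),
              orientation = runif(1, 0, pi), phase = runif(1, 0, 2 * pi))
    mask <- matrix(FALSE, 64, 64)
    halo <- matrix(FALSE, 64, 64)
    res <- agnorfd:::.try_place_dot(mask, halo, d$row, d$col, d$radius,
                                    d$aspect, d$amplitude, d$harmonics,
                                    d$orientation, d$phase)
    expect_true(res$accepted)
    ref <- oracle_raster_dot(64, d)
    got <- which(mask, arr.ind = TRUE)
    expect_equal(nrow(got), nrow(ref))
    expect_setequal(paste(got[, 1], got[, 2]), paste(ref[, 1], ref[, 2]))
    expect_equal(res$area, nrow(ref))
    expect_equal(res$centroid_r, mean(ref[, 1]) - 1)
    expect_equal(res$centroid_c, mean(ref[, 2]) - 1)
  }
})
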