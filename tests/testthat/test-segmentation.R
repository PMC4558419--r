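test_that("noise-free rendering is recovered dot for dot", {
  res <- generate_image(fixture_30_dots())
  expect_equal(nrow(res$truth$object_table), 30)
  mask <- segment_agnor(res$image)
  objs <- label_objects(mask)
  expect_equal(nrow(objs), 30)
  # centroid matching within 2 px against ground truth
  gt <- res$truth$object_table
  d2 <- outer(objs$centroid_r, gt$centroid_r, "-")^2 +
        outer(objs$centroid_c, gt$centroid_c, "-")^2
  expect_true(all(apply(d2, 2, min) <= 4))
  expect_true(all(apply(d2, 1, min) <= 4))
})

test_that("an all-white image yields an empty mask", {
  px <- array(255L, dim = c(64, 64, 3))
  mask <- segment_agnor(agnor_image(px, 0.17))
  expect_false(any(mask$pixels))
  expect_equal(nrow(label_objects(mask)), 0)
})

test_that("non-RGB input fails naming the offending shape", {
  expect_error(segment_agnor(matrix(0, 64, 64)), "\\[64, 64\\]")
})

test_that("dark green basal chromogen is excluded by the colour rule", {
  # render the band darker than the darkness threshold so only the green
  # exclusion rule can reject it
  cols <- list(dot = c(28, 25, 24), counterstain = c(205, 95, 90),
               basal = c(40, 120, 50), background = c(238, 227, 223))
  spec <- synthetic_spec(group = "BNH", arrangement = "glandular",
                         stain_colors = cols, noise_sd = 0, seed = 21)
  res <- generate_image(spec)
  # the band is present and dark
  px <- res$image$pixels
  band <- px[, , 2] == 120 & px[, , 1] == 40
  expect_gt(sum(band), 100)
  expect_lt(mean(px[, , 1][band] + px[, , 2][band] + px[, , 3][band]) / 3, 90)
  mask <- segment_agnor(res$image)
  expect_equal(sum(mask$pixels & band), 0)
  # and dots are still found
  expect_equal(nrow(label_objects(mask)),
               nrow(res$truth$object_table))
})

test_that("segmentation is deterministic and idempotent", {
  res <- generate_image(synthetic_spec(seed = 9))
  m1 <- segment_agnor(res$image)
  m2 <- segment_agnor(res$image)
  expect_identical(m1$pixels, m2$pixels)
  # re-render the mask as black-on-white and segment again
  px <- array(255L, dim = c(dim(m1$pixels), 3))
  for (ch in 1:3) {
    plane <- matrix(255L, nrow(m1$pixels), ncol(m1$pixels))
    plane[m1$pixels] <- 20L
    px[, , ch] <- plane
  }
  m3 <- segment_agnor(agnor_image(px, 0.17))
  expect_identical(m3$pixels, m1$pixels)
})

test_that("raising the minimum object size never increases the count", {
  res <- generate_image(synthetic_spec(seed = 13))
  counts <- vapply(c(1, 4, 10, 25, 60), function(mp) {
    nrow(label_objects(segment_agnor(res$image,
      segmentation_config(min_object_px = mp))))
  }, 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("labelling follows the 8-connected, raster-order convention", {
  m <- matrix(FALSE, 66, 66)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE         # diagonal touch: one object
  m[10, 10] <- TRUE                        # later in raster order
  lab <- label_components(m)
  expect_equal(max(lab), 2)
  expect_equal(lab[2, 2], lab[3, 3])
  expect_equal(lab[2, 2], 1L)              # first pixel row-major
  expect_equal(lab[10, 10], 2L)
  expect_equal(nrow(label_objects(binary_mask(m, "agnor"))), 2)
})

test_that("per-nucleus counts average over all nuclei and skip stromal dots", {
  # 3 nuclei with 2, 3, 4 dots -> mean 3
  objs <- tibble::tibble(
    centroid_r = c(rep(10, 2), rep(30, 3), rep(50, 4), 70),
    centroid_c = c(11, 12, rep(30, 3), rep(50, 4), 70))
  nm <- matrix(0L, 80, 80)
  nm[5:15, 5:15] <- 1L; nm[25:35, 25:35] <- 2L; nm[45:55, 45:55] <- 3L
  res <- count_per_nucleus(objs, nm)
  expect_equal(res$per_nucleus$count, c(2L, 3L, 4L))
  expect_equal(res$mean_per_nucleus, 3)
  expect_equal(res$unassigned, 1L)         # background centroid excluded
  expect_error(count_per_nucleus(objs, "no"), "matrix")
})

test_that("per-nucleus counts on synthetic images match the ground truth", {
  res <- generate_image(fixture_30_dots())
  objs <- label_objects(segment_agnor(res$image))
  got <- count_per_nucleus(objs, res$truth$nucleus_mask)
  truth_counts <- tabulate(res$truth$object_table$nucleus_id,
                           max(res$truth$nucleus_mask))
  expect_equal(got$per_nucleus$count, truth_counts)
})

test_that("compartment tagging requires a map and matches ground truth", {
  spec <- synthetic_spec(stromal_dots_mean = 6, noise_sd = 0, seed = 17)
  res <- generate_image(spec)
  objs <- label_objects(segment_agnor(res$image))
  expect_error(assign_compartment(objs, NULL), "compartment map")
  tagged <- assign_compartment(objs, res$truth$nucleus_mask)
  expect_true(all(tagged$compartment %in% c("epithelium", "stroma")))
  # match each object to its ground-truth row by nearest centroid
  gt <- res$truth$object_table
  near <- apply(outer(tagged$centroid_r, gt$centroid_r, "-")^2 +
                outer(tagged$centroid_c, gt$centroid_c, "-")^2, 1, which.min)
  expect_equal(tagged$compartment, gt$compartment[near])
  # empty object list stays empty
  empty <- label_objects(binary_mask(matrix(FALSE, 64, 64), "agnor"))
  expect_equal(nrow(assign_compartment(empty, res$truth$nucleus_mask)), 0)
})

test_that("segmentation survives realistic noise with high object fidelity", {
  hits <- 0; gt_n <- 0; seg_n <- 0
  for (s in 1:5) {
    res <- generate_image(synthetic_spec(noise_sd = 6, seed = 700 + s))
    objs <- label_objects(segment_agnor(res$image))
    gt <- res$truth$object_table
    if (!nrow(gt) || !nrow(objs)) next
    d2 <- outer(objs$centroid_r, gt$centroid_r, "-")^2 +
          outer(objs$centroid_c, gt$centroid_c, "-")^2
    hits <- hits + sum(apply(d2, 2, min) <= 4)
    gt_n <- gt_n + nrow(gt); seg_n <- seg_n + nrow(objs)
  }
  expect_gt(hits / gt_n, 0.95)   # recall
  expect_gt(hits / seg_n, 0.95)  # precision
})
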