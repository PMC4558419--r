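#' Roundness of an object (diameters ratio)
#'
#' Ratio of the major to the minor axis of the second-moment-equivalent
#' ellipse: the eigenvalue ratio of the pixel covariance matrix gives
#' (major/minor)^2. A circle scores 1; elongated objects score higher.
#' A small per-pixel variance correction (1/12 per axis) makes the
#' estimate usable for objects a few pixels across.
#'
#' Objects with fewer than 5 pixels do not define an ellipse fit and are
#' flagged degenerate (`NA`); the downstream value filter
#' ([filter_degenerate()]) removes them.
#'
#' An alternative isoperimetric formula, perimeter^2 / (4 pi area) with
#' the perimeter taken as the outline pixel count, is available as
#' `method = "circularity"`; the default diameters ratio is the reported
#' convention throughout the package.
#'
#' @param object_mask logical matrix containing one object (or a
#'   2-column matrix of pixel row/col coordinates).
#' @param method `"diameters_ratio"` (default) or `"circularity"`.
#' @return Roundness >= 1 (up to raster tolerance), or `NA_real_` when
#'   degenerate.
#' @examples
#' roundness(make_reference_shape("disk", side = 128, radius = 50)$pixels)
#' @export
roundness <- function(object_mask,
                      method = c("diameters_ratio", "circularity")) {
  method <- match.arg(method)
  if (is.matrix(object_mask) && ncol(object_mask) == 2L &&
      !is.logical(object_mask)) {
    pts <- object_mask
  } else {
    m <- as_mask_matrix(object_mask)
    sel <- which(m)
    nr <- nrow(m)
    pts <- cbind((sel - 1L) %% nr, (sel - 1L) %/% nr)
  }
  if (nrow(pts) < 5L) return(NA_real_)
  if (method == "circularity") {
    h <- diff(range(pts[, 1])) + 3L; w <- diff(range(pts[, 2])) + 3L
    mm <- matrix(FALSE, h, w)
    mm[cbind(pts[, 1] - min(pts[, 1]) + 2L, pts[, 2] - min(pts[, 2]) + 2L)] <- TRUE
    per <- sum(mm & !erode8(mm))
    return(per^2 / (4 * pi * nrow(pts)))
  }
  cv <- stats::cov(pts) * (nrow(pts) - 1) / nrow(pts)   # population moments
  cv[1, 1] <- cv[1, 1] + 1 / 12
  cv[2, 2] <- cv[2, 2] + 1 / 12
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] <= 0) return(NA_real_)
  sqrt(ev[1] / ev[2])
}

#' Calibrated object area
#'
#' @param pixel_area object area in pixels.
#' @param pixel_size micrometres per pixel.
#' @return A list with `pixel_area` and `area_um2`
#'   (= pixel_area x pixel_size^2).
#' @export
object_area <- function(pixel_area, pixel_size) {
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  list(pixel_area = pixel_area, area_um2 = pixel_area * pixel_size^2)
}

#' Measure all objects of a segmented image
#'
#' Computes, for every labelled object, its area (pixels and calibrated),
#' moment-ellipse roundness and boundary fractal dimension; optionally
#' tags compartments when a map is supplied.
#'
#' @param mask [binary_mask] from [segment_agnor()].
#' @param pixel_size micrometres per pixel.
#' @param compartment_map optional labelled/binary epithelium mask.
#' @param config [segmentation_config].
#' @return Tibble: one row per object with `label`, `pixel_area`,
#'   `area_um2`, `roundness`, `boundary_fd`, `fd_degenerate`,
#'   `centroid_r`, `centroid_c`, `compartment`.
#' @export
measure_objects <- function(mask, pixel_size = 0.17, compartment_map = NULL,
                            config = segmentation_config()) {
  m <- as_mask_matrix(mask)
  lab <- label_components(m)
  objs <- objects_from_labels(lab, nrow(m))
  n <- nrow(objs)
  rnd <- rep(NA_real_, n)
  bfd <- rep(1, n)
  deg <- rep(TRUE, n)
  if (n) {
    for (i in seq_len(n)) {
      # crop to the object's bounding box (1 px pad), then isolate its label
      rs <- (objs$bbox_r0[i] + 1L):(objs$bbox_r1[i] + 1L)
      cs <- (objs$bbox_c0[i] + 1L):(objs$bbox_c1[i] + 1L)
      core <- lab[rs, cs, drop = FALSE] == objs$label[i]
      patch <- matrix(FALSE, length(rs) + 2L, length(cs) + 2L)
      patch[2:(length(rs) + 1L), 2:(length(cs) + 1L)] <- core
      rnd[i] <- roundness(patch)
      f <- object_boundary_fd(patch)
      bfd[i] <- f$fd
      deg[i] <- f$degenerate
    }
  }
  out <- tibble::new_tibble(list(
    label = objs$label, pixel_area = objs$pixel_area,
    centroid_r = objs$centroid_r, centroid_c = objs$centroid_c,
    area_um2 = objs$pixel_area * pixel_size^2,
    roundness = rnd, boundary_fd = bfd, fd_degenerate = deg,
    compartment = rep("unknown", n)), nrow = n)
  if (!is.null(compartment_map))
    out <- assign_compartment(out, compartment_map)
  out
}

#' Remove degenerate measurement values
#'
#' The value filter applied before any statistics: objects with zero
#' area, undefined (or zero) roundness, or a boundary fractal dimension
#' equal to 1 (within 1e-6) are dropped. This removes the smallest,
#' unequivocally sub-resolution silver particles whose descriptors are
#' not meaningful. Order is preserved; the filter is idempotent.
#'
#' @param objects tibble from [measure_objects()].
#' @return Filtered tibble.
#' @export
filter_degenerate <- function(objects) {
  if (!nrow(objects)) return(objects)
  bad <- objects$pixel_area == 0 |
    is.na(objects$roundness) | objects$roundness == 0 |
    is.na(objects$boundary_fd) | abs(objects$boundary_fd - 1) < 1e-6
  objects[!bad, , drop = FALSE]
}

#' Per-image summary measurements
#'
#' Aggregates object measurements into the per-image quantities used by
#' the statistics layer: dot count, mean dots per nucleus, count density
#' per square millimetre, total normalized AgNOR-positive area (positive
#' pixels over total pixels, scaled by 1e6), mean roundness and mean
#' boundary FD over non-degenerate objects, and the skeleton FD of the
#' whole dot map. The value filter ([filter_degenerate()]) is applied to
#' the object set before averaging.
#'
#' @param objects tibble from [measure_objects()].
#' @param mask [binary_mask] the objects derive from.
#' @param image the source [agnor_image] (for calibration), or a
#'   pixel-size number.
#' @param nucleus_mask optional labelled nucleus mask for per-nucleus
#'   counts.
#' @param prune_length_px pruning length for the skeleton FD.
#' @param group optional group label to carry through.
#' @param compute_skeleton compute the whole-image skeleton FD (the most
#'   expensive per-image quantity); when `FALSE` the column is `NA`.
#' @return One-row tibble (class-compatible with row-binding across a
#'   cohort).
#' @export
image_summary <- function(objects, mask, image, nucleus_mask = NULL,
                          prune_length_px = 5L, group = NA_character_,
                          compute_skeleton = TRUE) {
  m <- as_mask_matrix(mask)
  if (inherits(image, "agnor_image")) {
    pixel_size <- image$pixel_size
    image_id <- image$image_id
  } else {
    pixel_size <- as.numeric(image)
    image_id <- if (inherits(mask, "binary_mask")) mask$source_image_id
                else NA_character_
  }
  kept <- filter_degenerate(objects)
  area_mm2 <- prod(dim(m)) * pixel_size^2 / 1e6
  mean_dpn <- NA_real_
  if (!is.null(nucleus_mask))
    mean_dpn <- count_per_nucleus(objects, nucleus_mask)$mean_per_nucleus
  sk <- if (compute_skeleton && any(m))
          skeleton_fd(m, prune_length_px = prune_length_px)
        else list(fd = NA_real_, degenerate = TRUE)
  tibble::new_tibble(list(
    image_id = image_id,
    group = group,
    dot_count = nrow(kept),
    mean_dots_per_nucleus = mean_dpn,
    density_per_mm2 = nrow(kept) / area_mm2,
    total_normalized_area = sum(m) / prod(dim(m)) * 1e6,
    mean_roundness = if (nrow(kept)) mean(kept$roundness) else NA_real_,
    mean_object_fd = if (any(!kept$fd_degenerate))
      mean(kept$boundary_fd[!kept$fd_degenerate]) else NA_real_,
    skeleton_fd = if (isTRUE(sk$degenerate)) NA_real_ else sk$fd), nrow = 1L)
}
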