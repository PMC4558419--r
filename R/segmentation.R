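#' Segmentation configuration
#'
#' Explicit, reproducible replacement for interactive "smart segmentation"
#' tools: AgNOR dots are dark against both the red nuclear counterstain
#' and the pale stroma, so a pixel is a candidate when its mean RGB
#' intensity falls below `darkness_threshold`; pixels dominated by the
#' green basal-cell chromogen are excluded; the mask is then cleaned by
#' morphological opening and a minimum-size filter.
#'
#' @param darkness_threshold maximum mean-RGB intensity (0-255) of a dot
#'   pixel.
#' @param green_margin a pixel is excluded as basal chromogen when its
#'   green channel exceeds both red and blue by more than this margin.
#' @param min_object_px smallest surviving component size, in pixels.
#' @param opening_radius_px radius of the morphological opening brush;
#'   0 disables opening.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(darkness_threshold = 90,
                                green_margin = 25,
                                min_object_px = 4L,
                                opening_radius_px = 0L) {
  if (darkness_threshold < 0 || darkness_threshold > 255)
    stop("darkness_threshold must lie in [0, 255]")
  if (min_object_px < 1) stop("min_object_px must be >= 1")
  if (opening_radius_px < 0) stop("opening_radius_px must be >= 0")
  structure(list(darkness_threshold = darkness_threshold,
                 green_margin = green_margin,
                 min_object_px = as.integer(min_object_px),
                 opening_radius_px = as.integer(opening_radius_px),
                 connectivity = 8L),
            class = "segmentation_config")
}

#' Segment AgNOR dots from an RGB image
#'
#' Extracts silver-stained dots as a binary mask: darkness thresholding
#' on the mean RGB intensity, exclusion of green-chromogen pixels,
#' optional morphological opening, and removal of components smaller than
#' `min_object_px` (8-connected). Deterministic.
#'
#' @param image an [agnor_image] (or a plain H x W x 3 array in 0-255).
#' @param config a [segmentation_config].
#' @return A [binary_mask] with provenance `"agnor"`.
#' @export
segment_agnor <- function(image, config = segmentation_config()) {
  if (inherits(image, "agnor_image")) {
    px <- image$pixels; id <- image$image_id
  } else {
    px <- image; id <- NA_character_
  }
  d <- dim(px)
  if (is.null(d) || length(d) != 3L || d[3] != 3L)
    stop("segment_agnor expects an RGB image; got dimensions [",
         paste(if (is.null(d)) length(px) else d, collapse = ", "), "]")
  r <- px[, , 1]; g <- px[, , 2]; b <- px[, , 3]
  dark <- (r + g + b) / 3 < config$darkness_threshold
  greenish <- g > pmax(r, b) + config$green_margin
  m <- dark & !greenish
  if (config$opening_radius_px > 0) {
    brush <- makeBrush(2L * config$opening_radius_px + 1L, shape = "disc")
    m <- imageData(opening(Image(m * 1), brush)) > 0
  }
  if (config$min_object_px > 1L && any(m)) {
    lab <- label_components(m)
    sizes <- tabulate(lab[lab > 0L])
    small <- which(sizes < config$min_object_px)
    if (length(small)) m[lab %in% small] <- FALSE
  }
  binary_mask(m, provenance = "agnor", source_image_id = id)
}

#' Label segmented dots and measure their basic geometry
#'
#' 8-connected labelling with stable raster order (components numbered by
#' their first pixel in a row-major scan), returning per-object pixel
#' area, centroid (0-based row/col) and bounding box.
#'
#' @param mask a [binary_mask] with provenance `"agnor"`.
#' @param config a [segmentation_config] (reserved for connectivity
#'   options; the default 8-connectivity is always used).
#' @return A tibble with columns `label`, `pixel_area`, `centroid_r`,
#'   `centroid_c`, `bbox_r0`, `bbox_r1`, `bbox_c0`, `bbox_c1`.
#' @export
label_objects <- function(mask, config = segmentation_config()) {
  if (inherits(mask, "binary_mask") && mask$provenance != "agnor")
    stop("label_objects expects a mask with provenance 'agnor'")
  m <- as_mask_matrix(mask)
  objects_from_labels(label_components(m), nrow(m))
}

# Shared core: per-object geometry from a labelled matrix.
objects_from_labels <- function(lab, nr) {
  n <- max(lab)
  if (n == 0L)
    return(tibble::new_tibble(list(
      label = integer(0), pixel_area = integer(0),
      centroid_r = numeric(0), centroid_c = numeric(0),
      bbox_r0 = integer(0), bbox_r1 = integer(0),
      bbox_c0 = integer(0), bbox_c1 = integer(0)), nrow = 0L))
  fg <- which(lab > 0L)
  rows <- (fg - 1L) %% nr           # 0-based row
  cols <- (fg - 1L) %/% nr          # 0-based col
  l <- lab[fg]
  area <- tabulate(l, n)
  tibble::new_tibble(list(
    label = seq_len(n),
    pixel_area = as.integer(area),
    centroid_r = as.numeric(rowsum(rows, l, reorder = TRUE)) / area,
    centroid_c = as.numeric(rowsum(cols, l, reorder = TRUE)) / area,
    bbox_r0 = as.integer(tapply(rows, l, min)),
    bbox_r1 = as.integer(tapply(rows, l, max)),
    bbox_c0 = as.integer(tapply(cols, l, min)),
    bbox_c1 = as.integer(tapply(cols, l, max))), nrow = n)
}

#' Per-nucleus dot counts
#'
#' Assigns each object to the nucleus label under its centroid and
#' averages counts over all nuclei present in the mask (nuclei without
#' dots contribute zeros). Objects whose centroid falls on background are
#' left unassigned and excluded from the mean.
#'
#' @param objects tibble from [label_objects()] (needs `centroid_r`,
#'   `centroid_c`).
#' @param nucleus_mask labelled integer matrix (0 = background).
#' @return A list with `per_nucleus` (tibble `nucleus_id`, `count`),
#'   `mean_per_nucleus`, and `unassigned` (number of objects on
#'   background).
#' @export
count_per_nucleus <- function(objects, nucleus_mask) {
  if (!is.matrix(nucleus_mask))
    stop("nucleus_mask must be a labelled integer matrix")
  n_nuc <- max(nucleus_mask, 0L)
  assigned <- integer(nrow(objects))
  if (nrow(objects)) {
    r <- pmin(pmax(round(objects$centroid_r) + 1L, 1L), nrow(nucleus_mask))
    c <- pmin(pmax(round(objects$centroid_c) + 1L, 1L), ncol(nucleus_mask))
    assigned <- nucleus_mask[cbind(r, c)]
  }
  counts <- tabulate(assigned[assigned > 0L], n_nuc)
  list(per_nucleus = tibble::tibble(nucleus_id = seq_len(n_nuc),
                                    count = as.integer(counts)),
       mean_per_nucleus = if (n_nuc > 0L) mean(counts) else NA_real_,
       unassigned = sum(assigned == 0L))
}

#' Tag objects with their tissue compartment
#'
#' Every object is tagged `"epithelium"` when its centroid lies inside an
#' epithelial region (a labelled or binary nucleus/epithelium mask) and
#' `"stroma"` otherwise; the complete tissue is their union. A compartment
#' map must be supplied — no heuristic guessing.
#'
#' @param objects tibble from [label_objects()].
#' @param compartment_map labelled nucleus mask or binary epithelium
#'   matrix (e.g. `truth$nucleus_mask` from [generate_image()]).
#' @return `objects` with an added `compartment` column.
#' @export
assign_compartment <- function(objects, compartment_map) {
  if (missing(compartment_map) || is.null(compartment_map))
    stop("a compartment map is required to assign compartments")
  if (!is.matrix(compartment_map))
    stop("compartment_map must be a matrix")
  if (!nrow(objects)) {
    objects$compartment <- character(0)
    return(objects)
  }
  r <- pmin(pmax(round(objects$centroid_r) + 1L, 1L), nrow(compartment_map))
  c <- pmin(pmax(round(objects$centroid_c) + 1L, 1L), ncol(compartment_map))
  inside <- compartment_map[cbind(r, c)] > 0
  objects$compartment <- ifelse(inside, "epithelium", "stroma")
  objects
}
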