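#' Calibrated RGB histology image
#'
#' Lightweight container for a brightfield RGB image together with its
#' spatial calibration. Pixel intensities are integers in \[0, 255\] stored
#' as an H x W x 3 array (rows = image rows).
#'
#' @param pixels integer array of dimension H x W x 3 with values in
#'   \[0, 255\]. H and W must both be at least 64.
#' @param pixel_size physical pixel size in micrometres per pixel (> 0).
#' @param kind acquisition kind: `"single"` for one high-magnification
#'   frame, `"composite"` for a grid merge of objective fields.
#' @param image_id opaque identifier string.
#' @param tile_size for composites, the side length (px) of one tile;
#'   H and W must then be exact multiples of it.
#'
#' @return An object of class `agnor_image`: a list with elements
#'   `pixels`, `pixel_size`, `kind`, `image_id` and (composites only)
#'   `tile_size`.
#' @export
agnor_image <- function(pixels, pixel_size, kind = c("single", "composite"),
                        image_id = "image", tile_size = NULL) {
  kind <- match.arg(kind)
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L)
    stop("'pixels' must be an H x W x 3 array; got dimensions [",
         paste(d, collapse = ", "), "]")
  if (d[1] < 64L || d[2] < 64L)
    stop("image must be at least 64 x 64 pixels")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("pixel intensities must lie in [0, 255]")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("'pixel_size' must be a single positive number (micrometres/pixel)")
  if (kind == "composite") {
    if (is.null(tile_size))
      stop("composite images require 'tile_size'")
    if (d[1] %% tile_size != 0L || d[2] %% tile_size != 0L)
      stop("composite dimensions must be exact multiples of tile_size")
  }
  structure(list(pixels = pixels, pixel_size = pixel_size, kind = kind,
                 image_id = as.character(image_id), tile_size = tile_size),
            class = "agnor_image")
}

#' @export
print.agnor_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<agnor_image '%s'> %d x %d px, %.3f um/px, kind = %s\n",
              x$image_id, d[1], d[2], x$pixel_size, x$kind))
  invisible(x)
}

#' Binary mask with provenance
#'
#' @param pixels logical H x W matrix.
#' @param provenance one of `"agnor"` (segmented dot mask), `"skeleton"`,
#'   `"reference"` (analytic calibration shape).
#' @param source_image_id identifier of the image the mask derives from.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, provenance = c("agnor", "skeleton", "reference"),
                        source_image_id = NA_character_) {
  provenance <- match.arg(provenance)
  if (!is.matrix(pixels) || !is.logical(pixels))
    stop("'pixels' must be a logical matrix")
  structure(list(pixels = pixels, provenance = provenance,
                 source_image_id = source_image_id),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d, %d foreground px, provenance = %s\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels), x$provenance))
  invisible(x)
}

# Coerce a binary_mask or logical matrix to a logical matrix.
as_mask_matrix <- function(mask) {
  if (inherits(mask, "binary_mask")) return(mask$pixels)
  if (is.matrix(mask) && is.logical(mask)) return(mask)
  if (is.matrix(mask) && is.numeric(mask)) return(mask > 0)
  stop("expected a binary_mask or a logical matrix")
}

#' Diagnostic group labels
#'
#' The six diagnostic categories compared throughout the package: benign
#' nodular hyperplasia (BNH), atypical adenomatous hyperplasia (AAH) and
#' acinar adenocarcinoma of Gleason patterns 2-5 (G2-G5).
#'
#' @return Character vector of the six labels, in fixed order.
#' @export
group_labels <- function() c("BNH", "AAH", "G2", "G3", "G4", "G5")

#' Is a group label a carcinoma pattern?
#'
#' Pooling predicate: the carcinoma pool is the union of Gleason patterns
#' 2 through 5; BNH and AAH are non-malignant.
#'
#' @param group character vector of group labels.
#' @return Logical vector.
#' @export
is_carcinoma <- function(group) {
  bad <- setdiff(unique(group), group_labels())
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  group %in% c("G2", "G3", "G4", "G5")
}
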