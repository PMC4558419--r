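#' Analytic reference shapes for estimator calibration
#'
#' Rasterizes analytic shapes onto binary masks. These fixtures calibrate
#' the box-counting fractal-dimension estimator and the moment-based
#' roundness measure against cases with known answers: a straight line
#' (FD = 1), a filled square (FD = 2), the order-k Sierpinski triangle
#' (FD = log 3 / log 2), smooth disks and ellipses, and "rugged blobs" —
#' disks whose boundary radius is perturbed as
#' r(theta) = R (1 + a sin(h theta + phase)), the same boundary model the
#' synthetic dot generator uses.
#'
#' Pixel centers sit at integer coordinates (0-based, row-major); a pixel
#' is foreground when its center satisfies the shape's inequality.
#'
#' @param kind one of `"line"`, `"disk"`, `"ellipse"`, `"filled_square"`,
#'   `"sierpinski"`, `"rugged_blob"`.
#' @param side mask side length in pixels (square mask). Fractal
#'   calibration fixtures should use `side >= 256`.
#' @param ... shape parameters: `length` (line); `radius` (disk,
#'   rugged_blob); `semi_major`, `semi_minor`, `angle` in radians
#'   (ellipse); `order` (sierpinski); `amplitude`, `harmonics`, `phase`
#'   (rugged_blob).
#'
#' @return A [binary_mask] with provenance `"reference"`.
#' @examples
#' disk <- make_reference_shape("disk", side = 128, radius = 50)
#' sum(disk$pixels) / (pi * 50^2)  # close to 1
#' @export
make_reference_shape <- function(kind, side = 512, ...) {
  params <- list(...)
  kinds <- c("line", "disk", "ellipse", "filled_square", "sierpinski",
             "rugged_blob")
  if (!is.character(kind) || length(kind) != 1L || !(kind %in% kinds))
    stop("unknown reference shape kind: ", deparse(substitute(kind)),
         " (", paste(kinds, collapse = ", "), " are supported)")
  side <- as.integer(side)
  m <- switch(kind,
    line = {
      len <- as.integer(params$length %||% side)
      if (len > side) side <- len
      m <- matrix(FALSE, side, side)
      m[side %/% 2L, seq_len(len)] <- TRUE
      m
    },
    disk = {
      R <- params$radius %||% (side / 4)
      raster_radial(side, function(theta) rep(R, length(theta)))
    },
    ellipse = {
      a <- params$semi_major %||% (side / 4)
      b <- params$semi_minor %||% (a / 2)
      ang <- params$angle %||% 0
      cc <- (side - 1) / 2
      x <- matrix(rep(0:(side - 1), each = side), side) - cc   # col coord
      y <- matrix(rep(0:(side - 1), side), side) - cc          # row coord
      u <- x * cos(ang) + y * sin(ang)
      v <- -x * sin(ang) + y * cos(ang)
      (u / a)^2 + (v / b)^2 <= 1
    },
    filled_square = matrix(TRUE, side, side),
    sierpinski = {
      order <- as.integer(params$order %||% 7L)
      n <- 2L^order
      if (side %% n != 0L)
        stop("side must be a multiple of 2^order for the sierpinski shape")
      # Pascal-triangle-mod-2 construction: cell (i, j) occupied iff the
      # binary expansions of i and j share no set bit; exactly 3^order cells.
      idx <- 0:(n - 1L)
      cells <- outer(idx, idx, function(i, j) bitwAnd(i, j) == 0L)
      k <- side %/% n
      cells[rep(seq_len(n), each = k), rep(seq_len(n), each = k)]
    },
    rugged_blob = {
      R <- params$radius %||% (side / 4)
      a <- params$amplitude %||% 0.2
      h <- params$harmonics %||% 8L
      ph <- params$phase %||% 0
      if (a < 0 || a > 0.5) stop("rugged_blob amplitude must lie in [0, 0.5]")
      raster_radial(side, function(theta) R * (1 + a * sin(h * theta + ph)))
    })
  binary_mask(m, provenance = "reference",
              source_image_id = paste0("reference:", kind))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Rasterize a star-convex region given its radial boundary function
# r(theta), centered at the mask center.
raster_radial <- function(side, radius_fun, center = NULL) {
  if (is.null(center)) center <- c((side - 1) / 2, (side - 1) / 2)
  row <- matrix(rep(0:(side - 1), side), side) - center[1]
  col <- matrix(rep(0:(side - 1), each = side), side) - center[2]
  r <- sqrt(row^2 + col^2)
  theta <- atan2(row, col)
  r <= radius_fun(theta)
}
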