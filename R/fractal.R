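#' Box-counting fractal dimension of a binary mask
#'
#' Classic grid estimator: for each box size the mask's foreground pixels
#' are binned into an axis-aligned grid and the number of occupied boxes
#' counted; to reduce grid-placement bias the count at each size is the
#' minimum over several grid offsets. The fractal dimension is the slope
#' of the least-squares fit of log(count) against log(1/size).
#'
#' Default box sizes are powers of two from 2 px up to a quarter of the
#' smaller mask side, which spans at least three octaves on masks of
#' side 256 and larger.
#'
#' @param mask a [binary_mask] or logical matrix; must contain foreground.
#' @param sizes decreasing or increasing vector of box sizes (>= 3 sizes).
#' @param offsets_per_size number of grid offsets per axis combined into
#'   the diagonal offset set; the count used is the minimum across them.
#' @return An object of class `box_count_result`: list with `box_sizes`,
#'   `counts`, `fd`, `r_squared`, `n_scales`.
#' @examples
#' sq <- make_reference_shape("filled_square", side = 256)
#' box_count_fd(sq)$fd  # about 2
#' @export
box_count_fd <- function(mask, sizes = NULL, offsets_per_size = 4L) {
  m <- as_mask_matrix(mask)
  fg <- which(m)
  if (!length(fg))
    stop("box_count_fd: empty mask has no fractal dimension")
  if (is.null(sizes)) {
    smax <- floor(min(dim(m)) / 4)
    if (smax < 8) stop("mask too small for the default box-size ladder")
    sizes <- 2^(1:floor(log2(smax)))
  }
  sizes <- sort(unique(as.integer(sizes)), decreasing = TRUE)
  if (length(sizes) < 3L)
    stop("box_count_fd needs at least 3 box sizes; got ", length(sizes))
  nr <- nrow(m)
  r <- (fg - 1L) %% nr          # 0-based coordinates
  c <- (fg - 1L) %/% nr
  # anchor the grid at the content's bounding box: counts (and hence the
  # fitted dimension) become exactly invariant under mask translation
  r <- r - min(r)
  c <- c - min(c)
  counts <- integer(length(sizes))
  for (i in seq_along(sizes)) {
    s <- sizes[i]
    offs <- unique(floor(s * (seq_len(offsets_per_size) - 1L) /
                           offsets_per_size))
    best <- Inf
    mult <- ncol(m) %/% s + 3L      # > any box column index
    for (or in offs) {
      br <- (r + or) %/% s
      for (oc in offs) {
        bc <- (c + oc) %/% s
        n <- length(unique(br * mult + bc))
        if (n < best) best <- n
      }
    }
    counts[i] <- best
  }
  x <- log(1 / sizes)
  y <- log(counts)
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- unname(fit$coefficients[2])
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else 1
  structure(list(box_sizes = sizes, counts = counts, fd = slope,
                 r_squared = r2, n_scales = length(sizes)),
            class = "box_count_result")
}

#' @export
print.box_count_result <- function(x, ...) {
  cat(sprintf("<box_count_result> fd = %.4f (R^2 = %.4f, %d scales %d..%d px)\n",
              x$fd, x$r_squared, x$n_scales, min(x$box_sizes),
              max(x$box_sizes)))
  invisible(x)
}

#' Boundary (silhouette) fractal dimension of one object
#'
#' The object's outline — the set difference between the mask and its
#' one-pixel 8-connected erosion — is box-counted on the object's padded
#' bounding box with sizes 1, 2, 4, ... up to half the box side. Small
#' smooth dots give values slightly above 1; rugged boundaries give
#' larger values. Objects too small to support three scales (or with a
#' boundary of fewer than 8 pixels) are flagged degenerate with FD = 1,
#' the sentinel value that the downstream value filter removes.
#'
#' @param object_mask logical matrix containing a single object.
#' @return A list with `fd` (1 exactly when degenerate), `degenerate`
#'   (logical), and `fit` (the [box_count_fd()] result or NULL).
#' @export
object_boundary_fd <- function(object_mask) {
  m <- as_mask_matrix(object_mask)
  sel <- which(m)
  degenerate <- list(fd = 1, degenerate = TRUE, fit = NULL)
  if (!length(sel)) return(degenerate)
  nr <- nrow(m)
  r <- (sel - 1L) %% nr + 1L
  c <- (sel - 1L) %/% nr + 1L
  h <- max(r) - min(r) + 3L; w <- max(c) - min(c) + 3L
  mm <- matrix(FALSE, h, w)
  mm[cbind(r - min(r) + 2L, c - min(c) + 2L)] <- TRUE
  boundary <- mm & !erode8(mm)
  if (sum(boundary) < 8L) return(degenerate)
  smax <- floor(min(h, w) / 2)
  if (smax < 4) return(degenerate)
  sizes <- 2^(0:floor(log2(smax)))
  if (length(sizes) < 3L) return(degenerate)
  fit <- box_count_fd(boundary, sizes = sizes)
  list(fd = fit$fd, degenerate = FALSE, fit = fit)
}

# --- skeletonization --------------------------------------------------

# One Zhang-Suen sub-iteration; which = 1L or 2L. Returns updated 0/1 matrix.
zs_subiter <- function(m, which) {
  # neighbours in Zhang-Suen order P2..P9 = N, NE, E, SE, S, SW, W, NW
  # (with image rows growing downward).
  p <- list(shift_mat(m, 1, 0), shift_mat(m, 1, -1), shift_mat(m, 0, -1),
            shift_mat(m, -1, -1), shift_mat(m, -1, 0), shift_mat(m, -1, 1),
            shift_mat(m, 0, 1), shift_mat(m, 1, 1))
  B <- p[[1]] + p[[2]] + p[[3]] + p[[4]] + p[[5]] + p[[6]] + p[[7]] + p[[8]]
  A <- matrix(0L, nrow(m), ncol(m))
  for (k in 1:8) {
    nxt <- p[[k %% 8 + 1]]
    A <- A + (p[[k]] == 0L & nxt == 1L)
  }
  if (which == 1L) {
    c3 <- p[[1]] * p[[3]] * p[[5]] == 0L
    c4 <- p[[3]] * p[[5]] * p[[7]] == 0L
  } else {
    c3 <- p[[1]] * p[[3]] * p[[7]] == 0L
    c4 <- p[[1]] * p[[5]] * p[[7]] == 0L
  }
  del <- m == 1L & B >= 2L & B <= 6L & A == 1L & c3 & c4
  m[del] <- 0L
  m
}

#' Skeletonize a dot mask and prune short spurs
#'
#' Topology-preserving Zhang-Suen thinning to a one-pixel-wide skeleton,
#' followed by iterative removal of endpoint pixels (`prune_length_px`
#' rounds), which deletes spur branches shorter than the pruning length.
#' Every connected component retains at least one pixel, so the component
#' count of the skeleton equals that of the source mask.
#'
#' @param mask a [binary_mask] with provenance `"agnor"`, or a logical
#'   matrix.
#' @param prune_length_px number of endpoint-erosion rounds (default 5).
#' @return An object of class `skeleton_map`: list with `mask` (a
#'   [binary_mask], provenance `"skeleton"`), `prune_length_px`,
#'   `component_count`.
#' @export
skeletonize_prune <- function(mask, prune_length_px = 5L) {
  if (inherits(mask, "binary_mask") && !mask$provenance %in% c("agnor", "reference"))
    stop("skeletonize_prune expects an AgNOR (or reference) mask")
  src_id <- if (inherits(mask, "binary_mask")) mask$source_image_id else NA_character_
  src <- as_mask_matrix(mask)
  src_lab <- label_components(src)
  m <- src * 1L
  repeat {
    m1 <- zs_subiter(m, 1L)
    m2 <- zs_subiter(m1, 2L)
    if (identical(m2, m)) break
    m <- m2
  }
  # spur pruning: iteratively shave endpoint pixels
  for (iter in seq_len(prune_length_px)) {
    endpoints <- m == 1L & neighbor_count8(m) == 1L
    if (!any(endpoints)) break
    m[endpoints] <- 0L
  }
  skel <- m > 0L
  # thinning can consume small compact blobs entirely (and pruning short
  # skeletons); restore one pixel per vanished component -- the foreground
  # pixel nearest the component centroid, i.e. its medial residue -- so
  # the skeleton has exactly one component per source component
  n_src <- max(src_lab)
  if (n_src > 0L) {
    missing <- setdiff(seq_len(n_src), unique(src_lab[skel]))
    if (length(missing)) {
      fg <- which(src_lab > 0L)
      lab_fg <- src_lab[fg]
      nr <- nrow(src)
      r <- (fg - 1L) %% nr
      c <- (fg - 1L) %/% nr
      for (d in missing) {
        sel <- lab_fg == d
        dr <- r[sel] - mean(r[sel]); dc <- c[sel] - mean(c[sel])
        skel[fg[sel][which.min(dr^2 + dc^2)]] <- TRUE
      }
    }
  }
  structure(list(mask = binary_mask(skel, provenance = "skeleton",
                                    source_image_id = src_id),
                 prune_length_px = as.integer(prune_length_px),
                 component_count = max(label_components(skel))),
            class = "skeleton_map")
}

#' Fractal dimension of the skeleton-filtered dot map
#'
#' Reduces the whole-image dot mask to its pruned skeleton and estimates
#' the box-counting fractal dimension of the result. This captures the
#' spatial repartition of the dots (glandular versus disorganized
#' architecture) rather than the shape of individual dots.
#'
#' @param dot_mask whole-image binary dot mask ([binary_mask] or logical
#'   matrix); must be non-empty.
#' @param prune_length_px pruning length passed to [skeletonize_prune()].
#' @param sizes optional box-size ladder for [box_count_fd()].
#' @return A list with `fd`, `degenerate` (TRUE when the skeleton cannot
#'   support three scales; `fd` is then 1), `skeleton` (the
#'   `skeleton_map`), and `fit`.
#' @export
skeleton_fd <- function(dot_mask, prune_length_px = 5L, sizes = NULL) {
  m <- as_mask_matrix(dot_mask)
  if (!any(m)) stop("skeleton_fd: empty dot mask")
  if (is.null(sizes)) {
    # coarse-scale ladder: the skeleton map measures how dots repartition
    # across the field, so boxes start above the size of one dot skeleton
    smax <- floor(min(dim(m)) / 4)
    if (smax >= 32) sizes <- 2^(3:floor(log2(smax)))
  }
  sk <- skeletonize_prune(m, prune_length_px = prune_length_px)
  skm <- sk$mask$pixels
  if (sum(skm) < 8L)   # a lone dot's skeleton carries no architecture
    return(list(fd = 1, degenerate = TRUE, skeleton = sk, fit = NULL))
  fit <- tryCatch(box_count_fd(skm, sizes = sizes), error = function(e) NULL)
  if (is.null(fit))
    return(list(fd = 1, degenerate = TRUE, skeleton = sk, fit = NULL))
  list(fd = fit$fd, degenerate = FALSE, skeleton = sk, fit = fit)
}
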