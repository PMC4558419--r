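# Connected-component labeling and small raster helpers.
#
# Convention used throughout: foreground is 8-connected, background
# 4-connected (the standard pairing that avoids topological paradoxes for
# dot-like objects). EBImage::bwlabel is 4-connected, so 8-connectivity is
# obtained by merging 4-connected labels that touch diagonally.

# Shift a matrix by (dr, dc), padding with `fill`.
shift_mat <- function(m, dr, dc, fill = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Number of 8-neighbours of each foreground pixel (0/1 input matrix).
neighbor_count8 <- function(m) {
  s <- matrix(0L, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    s <- s + shift_mat(m, dr, dc)
  }
  s
}

#' Label 8-connected components of a binary mask
#'
#' Labels are assigned in raster order: component 1 contains the first
#' foreground pixel met when scanning rows top-to-bottom, left-to-right.
#'
#' @param mask logical matrix or [binary_mask].
#' @return Integer matrix of the same size; 0 = background.
#' @export
label_components <- function(mask) {
  m <- as_mask_matrix(mask)
  relabel_raster_order(.label_components8(m))
}

# Renumber labels 1..k in row-major order of each component's first pixel.
relabel_raster_order <- function(lab) {
  fg <- which(lab > 0L)
  if (!length(fg)) return(lab)
  nr <- nrow(lab)
  r <- (fg - 1L) %% nr
  c <- (fg - 1L) %/% nr
  rowmajor <- r * ncol(lab) + c
  first <- tapply(rowmajor, lab[fg], min)
  ord <- order(first)
  remap <- integer(max(lab))
  remap[as.integer(names(first))[ord]] <- seq_along(ord)
  lab[fg] <- remap[lab[fg]]
  lab
}

# 1-pixel erosion with the full 3x3 (8-neighbour) structuring element;
# image border counts as background.
erode8 <- function(m) {
  keep <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    keep <- keep & shift_mat(m, dr, dc, fill = FALSE)
  }
  keep
}
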