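#' Specification of a synthetic histology image
#'
#' Parameter bundle for the synthetic image generator. The generator
#' emulates the appearance of combined silver / immunohistochemical
#' staining of prostate tissue: near-black AgNOR dots inside red
#' counterstained nuclei, a green basal-cell chromogen band around benign
#' glands, and a pale stromal background. Dots are rendered as ellipses
#' whose boundary radius is perturbed sinusoidally,
#' r(theta) = R (1 + a sin(h theta + phase)), so that a single amplitude
#' parameter controls the boundary complexity (and hence the silhouette
#' fractal dimension) while the aspect-ratio parameter controls roundness.
#'
#' @param group diagnostic group label (one of [group_labels()]); benign
#'   groups (BNH, AAH) receive a green basal band around each gland.
#' @param dots_per_nucleus_mean Poisson mean of AgNOR dots per nucleus.
#' @param nuclei_per_image number of epithelial nuclei per frame (per tile
#'   for composites).
#' @param dot_radius_px mean equivalent radius of a dot in pixels; the
#'   realised radius varies uniformly by +/- 20 percent.
#' @param aspect_ratio_mean mean major/minor axis ratio of the dot
#'   ellipses (>= 1; 1 = circles).
#' @param ruggedness_amplitude relative radial boundary perturbation, in
#'   \[0, 0.5\].
#' @param ruggedness_harmonics integer >= 2, angular frequency of the
#'   boundary perturbation.
#' @param arrangement `"glandular"` (nuclei on ring contours around gland
#'   lumina) or `"disorganized"` (uniform placement).
#' @param stain_colors list with RGB triples `dot`, `counterstain`,
#'   `basal`, `background` (0-255).
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @param stromal_dots_mean Poisson mean of extraglandular (stromal)
#'   silver dots per frame.
#' @param image_size frame (or composite tile) side length in pixels.
#' @param nucleus_radius_px mean nucleus radius in pixels.
#' @param pixel_size micrometres per pixel.
#' @param kind `"single"` or `"composite"` (a 4 x 6 grid of tiles,
#'   emulating merged high-magnification fields).
#' @param seed integer seed; identical spec + seed gives bit-identical
#'   output.
#'
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(group = "BNH",
                           dots_per_nucleus_mean = 3,
                           nuclei_per_image = 8,
                           dot_radius_px = 4.5,
                           aspect_ratio_mean = 1.3,
                           ruggedness_amplitude = 0.15,
                           ruggedness_harmonics = 9L,
                           arrangement = c("glandular", "disorganized"),
                           stain_colors = NULL,
                           noise_sd = 4,
                           stromal_dots_mean = 1,
                           image_size = 256L,
                           nucleus_radius_px = 20,
                           pixel_size = 0.17,
                           kind = c("single", "composite"),
                           seed = 1L) {
  arrangement <- match.arg(arrangement)
  kind <- match.arg(kind)
  if (is.null(stain_colors))
    stain_colors <- list(dot = c(28, 25, 24), counterstain = c(205, 95, 90),
                         basal = c(70, 170, 90), background = c(238, 227, 223))
  spec <- structure(list(
    group = group, dots_per_nucleus_mean = dots_per_nucleus_mean,
    nuclei_per_image = as.integer(nuclei_per_image),
    dot_radius_px = dot_radius_px, aspect_ratio_mean = aspect_ratio_mean,
    ruggedness_amplitude = ruggedness_amplitude,
    ruggedness_harmonics = as.integer(ruggedness_harmonics),
    arrangement = arrangement, stain_colors = stain_colors,
    noise_sd = noise_sd, stromal_dots_mean = stromal_dots_mean,
    image_size = as.integer(image_size),
    nucleus_radius_px = nucleus_radius_px, pixel_size = pixel_size,
    kind = kind, seed = as.integer(seed)), class = "synthetic_spec")
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  with(spec, {
    if (!(group %in% group_labels()))
      stop("unknown group label: ", group)
    if (dots_per_nucleus_mean < 0) stop("dots_per_nucleus_mean must be >= 0")
    if (nuclei_per_image < 1) stop("nuclei_per_image must be >= 1")
    if (dot_radius_px <= 0) stop("dot_radius_px must be > 0")
    if (aspect_ratio_mean < 1) stop("aspect_ratio_mean must be >= 1")
    if (ruggedness_amplitude < 0 || ruggedness_amplitude > 0.5)
      stop("ruggedness_amplitude must lie in [0, 0.5]")
    if (ruggedness_harmonics < 2) stop("ruggedness_harmonics must be >= 2")
    if (noise_sd < 0) stop("noise_sd must be >= 0")
    if (image_size < 64) stop("image_size must be >= 64")
    if (pixel_size <= 0) stop("pixel_size must be > 0")
  })
  invisible(spec)
}

# Run expr under a given seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate one synthetic histology image with ground truth
#'
#' Renders the scene described by a [synthetic_spec] and returns both the
#' RGB image and exact ground truth (per-dot table, labelled nucleus mask,
#' binary dot mask). Dots are placed with a minimum boundary separation of
#' two pixels so that each ground-truth object is exactly one 8-connected
#' component of the dot mask.
#'
#' @param spec a [synthetic_spec].
#' @param image_id identifier stored in the image; defaults to a
#'   group/seed-derived string.
#' @return A list with elements `image` ([agnor_image]) and `truth`
#'   (class `ground_truth`: `object_table`, `nucleus_mask`, `dot_mask`,
#'   `group`).
#' @export
generate_image <- function(spec, image_id = NULL) {
  validate_synthetic_spec(spec)
  if (is.null(image_id))
    image_id <- sprintf("%s_seed%d", spec$group, spec$seed)
  if (spec$kind == "composite") {
    return(generate_composite(spec, image_id))
  }
  with_local_seed(spec$seed, render_tile(spec, image_id))
}

# Core renderer for a single frame. Assumes the RNG is already seeded.
render_tile <- function(spec, image_id, offset = c(0L, 0L)) {
  S <- spec$image_size
  rn <- spec$nucleus_radius_px
  cols <- spec$stain_colors

  scene <- place_nuclei(spec)
  nuc <- scene$nuclei            # data.frame: row, col, radius, gland
  glands <- scene$glands         # data.frame: row, col, ring_radius (or NULL)

  # --- masks -----------------------------------------------------------
  nucleus_mask <- matrix(0L, S, S)
  for (i in seq_len(nrow(nuc)))
    nucleus_mask <- paint_disk(nucleus_mask, nuc$row[i], nuc$col[i],
                               nuc$radius[i], i)

  band_mask <- matrix(FALSE, S, S)
  benign <- !is_carcinoma(spec$group)
  if (benign && spec$arrangement == "glandular" && !is.null(glands)) {
    for (g in seq_len(nrow(glands))) {
      r0 <- glands$ring_radius[g] + rn + 2
      band_mask <- band_mask | paint_annulus(S, glands$row[g], glands$col[g],
                                             r0, r0 + 4)
    }
    band_mask <- band_mask & nucleus_mask == 0L
  }

  # --- dots ------------------------------------------------------------
  placed <- place_and_raster_dots(spec, nuc, glands)
  dot_mask <- placed$dot_mask
  dots <- placed$table

  object_table <- tibble::new_tibble(list(
    object_id = seq_len(nrow(dots)),
    centroid_r = dots$centroid_r + offset[1],
    centroid_c = dots$centroid_c + offset[2],
    pixel_area = dots$pixel_area,
    true_aspect_ratio = dots$aspect,
    true_ruggedness_amplitude = dots$amplitude,
    nucleus_id = dots$nucleus_id,
    compartment = ifelse(is.na(dots$nucleus_id), "stroma", "epithelium")),
    nrow = nrow(dots))

  # --- rendering -------------------------------------------------------
  px <- array(0, dim = c(S, S, 3))
  for (ch in 1:3) {
    plane <- matrix(cols$background[ch], S, S)
    plane[nucleus_mask > 0L] <- cols$counterstain[ch]
    plane[band_mask] <- cols$basal[ch]
    plane[dot_mask] <- cols$dot[ch]
    px[, , ch] <- plane
  }
  if (spec$noise_sd > 0)
    px <- px + stats::rnorm(length(px), 0, spec$noise_sd)
  px <- round(pmin(pmax(px, 0), 255))
  storage.mode(px) <- "integer"

  image <- agnor_image(px, pixel_size = spec$pixel_size, kind = "single",
                       image_id = image_id)
  truth <- structure(list(object_table = object_table,
                          nucleus_mask = nucleus_mask,
                          dot_mask = dot_mask, group = spec$group),
                     class = "ground_truth")
  list(image = image, truth = truth)
}

# Place nuclei either on gland ring contours or uniformly, with rejection
# sampling; raises an error when the requested count cannot be packed.
place_nuclei <- function(spec) {
  S <- spec$image_size
  rn <- spec$nucleus_radius_px
  n <- spec$nuclei_per_image
  min_sep <- 2 * rn + 2

  if (spec$arrangement == "glandular") {
    per_gland <- 8L
    n_glands <- ceiling(n / per_gland)
    counts <- rep(n %/% n_glands, n_glands)
    if (sum(counts) < n) counts[seq_len(n - sum(counts))] <-
        counts[seq_len(n - sum(counts))] + 1L
    # ring radius chosen so the chord between adjacent nuclei exceeds the
    # separation minimum even after angular jitter
    ring <- pmax(ifelse(counts > 1,
                        min_sep / (2 * sin(pi / pmax(counts, 2))) * 1.06,
                        1.5 * rn), 1.8 * rn)
    extent <- ring + rn + 8          # ring + nucleus + basal band margin
    if (any(2 * extent + 2 >= S))
      stop("cannot place ", n_glands, " glands of extent ",
           round(max(extent)), " px in a ", S, " px frame: packing limit")
    centers <- NULL
    for (restart in seq_len(200)) {
      centers <- matrix(NA_real_, n_glands, 2)
      done <- TRUE
      for (g in seq_len(n_glands)) {
        ok <- FALSE
        for (try in seq_len(100)) {
          cand <- stats::runif(2, extent[g] + 1, S - extent[g] - 1)
          if (g == 1L || all(sqrt(rowSums((centers[seq_len(g - 1), , drop = FALSE] -
                matrix(cand, g - 1, 2, byrow = TRUE))^2)) >
                extent[g] + extent[seq_len(g - 1)])) { ok <- TRUE; break }
        }
        if (!ok) { done <- FALSE; break }
        centers[g, ] <- cand
      }
      if (done) break
      centers <- NULL
    }
    if (is.null(centers))
      stop("cannot place ", n_glands, " glands of extent ",
           round(max(extent)), " px in a ", S, " px frame: packing limit")
    rows <- numeric(0); cls <- numeric(0); gl <- integer(0)
    for (g in seq_len(n_glands)) {
      k <- counts[g]
      ang <- (seq_len(k) - 1) * 2 * pi / k + stats::runif(1, 0, 2 * pi) +
        stats::runif(k, -0.03, 0.03)
      rows <- c(rows, centers[g, 1] + ring[g] * sin(ang))
      cls <- c(cls, centers[g, 2] + ring[g] * cos(ang))
      gl <- c(gl, rep(g, k))
    }
    nuc <- data.frame(row = rows, col = cls,
                      radius = rn * stats::runif(n, 0.92, 1.08), gland = gl)
    glands <- data.frame(row = centers[, 1], col = centers[, 2],
                         ring_radius = ring)
  } else {
    lo <- rn + 2; hi <- S - rn - 1
    if (hi <= lo) stop("nucleus radius too large for frame: packing limit")
    rows <- numeric(n); cls <- numeric(n)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(400)) {
        cand <- stats::runif(2, lo, hi)
        if (i == 1L || all((rows[seq_len(i - 1)] - cand[1])^2 +
                           (cls[seq_len(i - 1)] - cand[2])^2 > min_sep^2)) {
          ok <- TRUE; break
        }
      }
      if (!ok) stop("cannot place ", n, " nuclei of radius ", rn, " in a ",
                    S, " px frame: packing limit")
      rows[i] <- cand[1]; cls[i] <- cand[2]
    }
    nuc <- data.frame(row = rows, col = cls,
                      radius = rn * stats::runif(n, 0.92, 1.08),
                      gland = NA_integer_)
    glands <- NULL
  }
  list(nuclei = nuc, glands = glands)
}

# Place and rasterize dots (intranuclear + stromal). Collision checking
# works on the rendered rasters: a candidate dot is accepted only when no
# pixel of it lies within Chebyshev distance 2 of an already-rendered dot,
# so every dot stays a separate 8-connected component of the mask.
place_and_raster_dots <- function(spec, nuc, glands) {
  S <- spec$image_size
  amp <- spec$ruggedness_amplitude
  dot_mask <- matrix(FALSE, S, S)
  # halo marks every pixel within Chebyshev distance 2 of a rendered dot;
  # a candidate is rejected when any of its pixels falls on the halo,
  # which guarantees a >= 2 px boundary gap between dots.
  halo <- matrix(FALSE, S, S)


  harm <- spec$ruggedness_harmonics
  acc_r <- numeric(0); acc_c <- numeric(0); acc_a <- integer(0)
  acc_asp <- numeric(0); acc_nuc <- integer(0)
  record <- function(res, asp, nucleus_id) {
    acc_r[length(acc_r) + 1L] <<- res$centroid_r
    acc_c[length(acc_c) + 1L] <<- res$centroid_c
    acc_a[length(acc_a) + 1L] <<- res$area
    acc_asp[length(acc_asp) + 1L] <<- asp
    acc_nuc[length(acc_nuc) + 1L] <<- nucleus_id
  }

  for (i in seq_len(nrow(nuc))) {
    k <- stats::rpois(1, spec$dots_per_nucleus_mean)
    if (k == 0L) next
    got <- .place_nucleus_dots(dot_mask, halo, nuc$row[i], nuc$col[i],
                               nuc$radius[i], k, spec$dot_radius_px,
                               spec$aspect_ratio_mean, amp, harm)
    if (length(got$pixel_area)) {
      acc_r <- c(acc_r, got$centroid_r)
      acc_c <- c(acc_c, got$centroid_c)
      acc_a <- c(acc_a, got$pixel_area)
      acc_asp <- c(acc_asp, got$aspect)
      acc_nuc <- c(acc_nuc, rep(i, length(got$pixel_area)))
    }
  }

  # stromal dots, kept clear of nuclei and basal bands
  ks <- stats::rpois(1, spec$stromal_dots_mean)
  for (j in seq_len(ks)) {
    for (try in seq_len(120)) {
      u <- stats::runif(5)
      R <- spec$dot_radius_px * (0.8 + 0.4 * u[1])
      asp <- 1 + (spec$aspect_ratio_mean - 1) * stats::rgamma(1, 6, 6)
      ori <- pi * u[2]
      phase <- 2 * pi * u[3]
      maxr <- R * sqrt(asp) * (1 + amp)
      if (maxr + 3 >= S / 2) break
      cand <- c(maxr + 2 + (S - 2 * maxr - 4) * u[4],
                maxr + 2 + (S - 2 * maxr - 4) * u[5])
      clear_nuc <- all(sqrt((nuc$row - cand[1])^2 + (nuc$col - cand[2])^2) >
                       nuc$radius + maxr + 3)
      clear_band <- TRUE
      if (!is.null(glands)) {
        dd <- sqrt((glands$row - cand[1])^2 + (glands$col - cand[2])^2)
        ring_out <- glands$ring_radius + spec$nucleus_radius_px + 6
        clear_band <- all(dd > ring_out + maxr + 3 |
                          dd < glands$ring_radius - spec$nucleus_radius_px -
                              maxr - 3)
      }
      if (!(clear_nuc && clear_band)) next
      res <- .try_place_dot(dot_mask, halo, cand[1], cand[2], R, asp,
                            amp, harm, ori, phase)
      if (res$accepted) { record(res, asp, NA_integer_); break }
    }
  }

  list(dot_mask = dot_mask,
       table = data.frame(centroid_r = acc_r, centroid_c = acc_c,
                          pixel_area = acc_a, aspect = acc_asp,
                          amplitude = rep(amp, length(acc_r)),
                          nucleus_id = acc_nuc))
}

paint_disk <- function(mask, row, col, radius, value) {
  S <- nrow(mask)
  r0 <- max(1L, floor(row - radius)); r1 <- min(S, ceiling(row + radius))
  c0 <- max(1L, floor(col - radius)); c1 <- min(S, ceiling(col + radius))
  rr <- (r0:r1) - row; cc <- (c0:c1) - col
  d2 <- outer(rr^2, cc^2, "+")
  sel <- which(d2 <= radius^2, arr.ind = TRUE)
  mask[cbind(sel[, 1] + r0 - 1L, sel[, 2] + c0 - 1L)] <- value
  mask
}

paint_annulus <- function(S, row, col, r_in, r_out) {
  m <- matrix(FALSE, S, S)
  r0 <- max(1L, floor(row - r_out)); r1 <- min(S, ceiling(row + r_out))
  c0 <- max(1L, floor(col - r_out)); c1 <- min(S, ceiling(col + r_out))
  if (r1 < r0 || c1 < c0) return(m)
  rr <- (r0:r1) - row; cc <- (c0:c1) - col
  d2 <- outer(rr^2, cc^2, "+")
  sel <- which(d2 >= r_in^2 & d2 <= r_out^2, arr.ind = TRUE)
  m[cbind(sel[, 1] + r0 - 1L, sel[, 2] + c0 - 1L)] <- TRUE
  m
}

# 4 x 6 grid of tiles merged into one composite capture.
generate_composite <- function(spec, image_id) {
  tiles_r <- 4L; tiles_c <- 6L
  S <- spec$image_size
  tile_seeds <- with_local_seed(spec$seed,
    sample.int(.Machine$integer.max - 1L, tiles_r * tiles_c))
  px <- array(0L, dim = c(tiles_r * S, tiles_c * S, 3))
  nucleus_mask <- matrix(0L, tiles_r * S, tiles_c * S)
  dot_mask <- matrix(FALSE, tiles_r * S, tiles_c * S)
  tabs <- list()
  nuc_off <- 0L
  for (tr in seq_len(tiles_r)) for (tc in seq_len(tiles_c)) {
    k <- (tr - 1L) * tiles_c + tc
    sub <- spec; sub$kind <- "single"; sub$seed <- tile_seeds[k]
    off <- c((tr - 1L) * S, (tc - 1L) * S)
    tile <- with_local_seed(sub$seed,
      render_tile(sub, paste0(image_id, "_t", k), offset = off))
    rows <- off[1] + seq_len(S); cls <- off[2] + seq_len(S)
    px[rows, cls, ] <- tile$image$pixels
    tm <- tile$truth$nucleus_mask
    tm[tm > 0L] <- tm[tm > 0L] + nuc_off
    nucleus_mask[rows, cls] <- tm
    dot_mask[rows, cls] <- tile$truth$dot_mask
    tab <- tile$truth$object_table
    tab$nucleus_id <- tab$nucleus_id + nuc_off
    tabs[[k]] <- tab
    nuc_off <- nuc_off + max(tile$truth$nucleus_mask)
  }
  object_table <- do.call(rbind, tabs)
  object_table$object_id <- seq_len(nrow(object_table))
  image <- agnor_image(px, pixel_size = spec$pixel_size, kind = "composite",
                       image_id = image_id, tile_size = S)
  truth <- structure(list(object_table = object_table,
                          nucleus_mask = nucleus_mask, dot_mask = dot_mask,
                          group = spec$group), class = "ground_truth")
  list(image = image, truth = truth)
}

#' Generate a multi-group synthetic cohort
#'
#' Produces `images_per_group` images for each of the six diagnostic
#' groups, with per-image seeds derived deterministically from the master
#' seed and images assigned to synthetic patients in blocks.
#'
#' @param specs_by_group named list mapping every label in
#'   [group_labels()] to a [synthetic_spec]; per-spec seeds are ignored
#'   and replaced by derived seeds.
#' @param images_per_group integer >= 1.
#' @param seed master seed.
#' @param images_per_patient block size for assigning synthetic patient
#'   identifiers (default 5 images per patient).
#' @return A list of elements `list(image, truth, group, patient_id)`, of
#'   length `6 * images_per_group`.
#' @export
generate_cohort <- function(specs_by_group, images_per_group, seed,
                            images_per_patient = 5L) {
  missing <- setdiff(group_labels(), names(specs_by_group))
  if (length(missing))
    stop("specs_by_group is missing group(s): ", paste(missing, collapse = ", "))
  if (images_per_group < 1) stop("images_per_group must be >= 1")
  seeds <- with_local_seed(seed,
    sample.int(.Machine$integer.max - 1L, 6L * images_per_group))
  out <- vector("list", 6L * images_per_group)
  k <- 0L
  for (g in group_labels()) {
    for (i in seq_len(images_per_group)) {
      k <- k + 1L
      sp <- specs_by_group[[g]]
      sp$group <- g
      sp$seed <- seeds[k]
      pid <- sprintf("%s_p%02d", g, (i - 1L) %/% images_per_patient + 1L)
      res <- generate_image(sp, image_id = sprintf("%s_i%03d", g, i))
      out[[k]] <- list(image = res$image, truth = res$truth, group = g,
                       patient_id = pid)
    }
  }
  out
}
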