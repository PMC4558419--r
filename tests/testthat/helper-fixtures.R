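# Shared fixtures, built in code at test time.

# Noise-free frame rendering exactly 30 dots across 10 nuclei (seed chosen
# so the Poisson draws and placement realise the 30-dot case).
fixture_30_dots <- function() {
  synthetic_spec(group = "BNH", nuclei_per_image = 10,
                 dots_per_nucleus_mean = 3, arrangement = "disorganized",
                 noise_sd = 0, stromal_dots_mean = 0, seed = 6)
}

# Small, fast per-group specs for cohort-level tests.
small_group_specs <- function(...) {
  default_group_specs(image_size = 128L, nuclei_per_image = 4L,
                      nucleus_radius_px = 15, dots_per_nucleus_mean = 2.5,
                      stromal_dots_mean = 0.5, ...)
}

# Identical-spec (null) cohort map at miniature scale.
null_group_specs <- function() {
  base <- synthetic_spec(group = "BNH", arrangement = "disorganized",
                         nuclei_per_image = 3, nucleus_radius_px = 10,
                         dots_per_nucleus_mean = 2, dot_radius_px = 3.5,
                         image_size = 72L, stromal_dots_mean = 0, noise_sd = 3)
  out <- lapply(group_labels(), function(g) { s <- base; s$group <- g; s })
  names(out) <- group_labels()
  out
}

# Union-of-disks mask (for skeleton repartition tests).
disks_mask <- function(side, centers, radius) {
  m <- matrix(FALSE, side, side)
  rr <- matrix(rep(1:side, side), side)
  cc <- matrix(rep(1:side, each = side), side)
  for (i in seq_len(nrow(centers)))
    m <- m | ((rr - centers[i, 1])^2 + (cc - centers[i, 2])^2 <= radius^2)
  m
}
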