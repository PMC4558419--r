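# Independent oracles used across the suite. Each reimplements the checked
# quantity by a different route than the package (queue flood fill, explicit
# sums of squares, exhaustive grid overlays) so agreement is informative.

# 8-connected component count by queue-based flood fill.
flood_fill_count <- function(mask) {
  m <- if (inherits(mask, "binary_mask")) mask$pixels else mask
  nr <- nrow(m); nc <- ncol(m)
  seen <- matrix(FALSE, nr, nc)
  count <- 0L
  for (start in which(m & !seen)) {
    if (seen[start]) next
    count <- count + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      r <- (i - 1L) %% nr + 1L; c <- (i - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        j <- (cc - 1L) * nr + rr
        if (m[j] && !seen[j]) { seen[j] <- TRUE; queue <- c(queue, j) }
      }
    }
  }
  count
}

# Second-moment axis ratio from explicit raw sums and the closed-form
# eigenvalues of a 2x2 symmetric matrix (no cov()/eigen()).
oracle_axis_ratio <- function(mask) {
  sel <- which(mask)
  nr <- nrow(mask)
  x <- (sel - 1) %% nr; y <- (sel - 1) %/% nr
  n <- length(sel)
  mx <- sum(x) / n; my <- sum(y) / n
  sxx <- sum((x - mx)^2) / n + 1 / 12
  syy <- sum((y - my)^2) / n + 1 / 12
  sxy <- sum((x - mx) * (y - my)) / n
  tr <- sxx + syy
  disc <- sqrt((sxx - syy)^2 + 4 * sxy^2)
  sqrt((tr + disc) / (tr - disc))
}

# Classical one-way ANOVA from explicit sums of squares.
oracle_anova <- function(values) {
  all <- unlist(values, use.names = FALSE)
  gm <- mean(all)
  k <- length(values)
  n <- length(all)
  ssb <- sum(vapply(values, function(v) length(v) * (mean(v) - gm)^2, 0))
  ssw <- sum(vapply(values, function(v) sum((v - mean(v))^2), 0))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(f_stat = f, df_between = k - 1, df_within = n - k,
       p_value = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

# Tukey-Kramer adjusted p-values from the studentized range distribution.
oracle_tukey <- function(values) {
  k <- length(values)
  n <- length(unlist(values))
  mse <- sum(vapply(values, function(v) sum((v - mean(v))^2), 0)) / (n - k)
  pairs <- utils::combn(names(values), 2)
  out <- data.frame(a = pairs[1, ], b = pairs[2, ], p = NA_real_)
  for (i in seq_len(ncol(pairs))) {
    va <- values[[pairs[1, i]]]; vb <- values[[pairs[2, i]]]
    se <- sqrt(mse / 2 * (1 / length(va) + 1 / length(vb)))
    q <- abs(mean(va) - mean(vb)) / se
    out$p[i] <- stats::ptukey(q, k, n - k, lower.tail = FALSE)
  }
  out
}

# Exhaustive grid-overlay occupied-box count: lays boxes of the given size
# over the (bounding-box-anchored) pixel cloud starting at -offset and
# tests interval membership for every box cell directly.
oracle_box_count <- function(mask, size, offset_r = 0L, offset_c = offset_r) {
  sel <- which(mask)
  nr <- nrow(mask)
  r <- (sel - 1) %% nr; c <- (sel - 1) %/% nr
  r <- r - min(r); c <- c - min(c)
  starts_r <- seq(-offset_r, max(r), by = size)
  starts_c <- seq(-offset_c, max(c), by = size)
  count <- 0L
  for (sr in starts_r) for (sc in starts_c) {
    if (any(r >= sr & r < sr + size & c >= sc & c < sc + size))
      count <- count + 1L
  }
  count
}

# Random grouped fixtures for statistics oracle checks.
random_group_fixture <- function(k = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(k)) k <- sample(2:6, 1)
  sizes <- sample(3:12, k, replace = TRUE)
  vals <- lapply(sizes, function(n) stats::rnorm(n, mean = stats::runif(1, -2, 2),
                                                 sd = stats::runif(1, 0.5, 2)))
  names(vals) <- paste0("g", seq_len(k))
  vals
}

# Reference rasterizer for one perturbed-ellipse dot (pure R), used to
# cross-check the compiled placement kernel. Returns 1-based pixel indices.
oracle_raster_dot <- function(S, d) {
  maxr <- d$radius * sqrt(d$aspect) * (1 + d$amplitude)
  r0 <- max(1L, floor(d$row - maxr)); r1 <- min(S, ceiling(d$row + maxr))
  c0 <- max(1L, floor(d$col - maxr)); c1 <- min(S, ceiling(d$col + maxr))
  rr <- (r0:r1) - d$row
  cc <- (c0:c1) - d$col
  dr <- matrix(rr, length(rr), length(cc))
  dc <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  rho <- sqrt(dr^2 + dc^2)
  theta <- atan2(dr, dc)
  A <- d$radius * sqrt(d$aspect); B <- d$radius / sqrt(d$aspect)
  t <- theta - d$orientation
  re <- A * B / sqrt((B * cos(t))^2 + (A * sin(t))^2)
  lim <- re * (1 + d$amplitude * sin(d$harmonics * theta + d$phase))
  sel <- which(rho <= lim, arr.ind = TRUE)
  cbind(sel[, 1] + r0 - 1L, sel[, 2] + c0 - 1L)
}
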