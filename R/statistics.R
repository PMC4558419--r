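#' Build a long-format cohort table
#'
#' @param image_id,patient_id,group,metric,value parallel vectors; one row
#'   per (image, metric) pair.
#' @param image_kind acquisition kind per row (default `"single"`).
#' @return A tibble of class `cohort_table`.
#' @export
cohort_table <- function(image_id, patient_id, group, metric, value,
                         image_kind = "single") {
  tab <- tibble::tibble(patient_id = patient_id, image_id = image_id,
                        image_kind = image_kind, group = group,
                        metric = metric, value = value)
  bad <- setdiff(unique(tab$group), group_labels())
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(tab[, c("image_id", "metric")]))
    stop("duplicate (image_id, metric) pairs in cohort table")
  class(tab) <- c("cohort_table", class(tab))
  tab
}

#' Hierarchical averaging of cohort measurements
#'
#' Values are averaged strictly hierarchically — images within a patient,
#' then patients within a group — never by pooling lower-level values
#' across units. Aggregating an unbalanced design to group level
#' therefore weights every patient equally regardless of how many images
#' they contributed.
#'
#' @param table a [cohort_table()] at image granularity.
#' @param level `"image"` (identity), `"patient"` or `"group"`.
#' @return A tibble with one row per unit and metric (`value` = mean).
#' @export
aggregate_cohort <- function(table, level = c("image", "patient", "group")) {
  level <- match.arg(level)
  if (level == "image") return(table)
  pat <- stats::aggregate(value ~ patient_id + group + metric, data = table,
                          FUN = mean)
  if (level == "patient")
    return(tibble::as_tibble(pat[order(pat$metric, pat$group, pat$patient_id), ]))
  grp <- stats::aggregate(value ~ group + metric, data = pat, FUN = mean)
  tibble::as_tibble(grp[order(grp$metric, grp$group), ])
}

# Normalize "values by group" inputs: named list of numeric vectors, or a
# data.frame with columns group/value.
values_by_group <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("group", "value") %in% names(x)))
    x <- split(x$value, x$group)
  }
  if (!is.list(x) || is.null(names(x)))
    stop("expected a named list of numeric vectors or a group/value data frame")
  lapply(x, function(v) as.numeric(v[is.finite(v)]))
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA via the between/within
#' sums-of-squares decomposition (fitted with [stats::aov()]).
#'
#' @param values named list of numeric vectors (one per group), or a data
#'   frame with `group` and `value` columns. Every group needs >= 2
#'   values.
#' @return List of class `anova_result`: `f_stat`, `df_between`,
#'   `df_within`, `p_value`.
#' @export
one_way_anova <- function(values) {
  vals <- values_by_group(values)
  if (length(vals) < 2L) stop("one_way_anova needs at least 2 groups")
  small <- names(vals)[vapply(vals, length, 1L) < 2L]
  if (length(small))
    stop("group(s) with fewer than 2 values: ", paste(small, collapse = ", "))
  df <- data.frame(value = unlist(vals, use.names = FALSE),
                   group = factor(rep(names(vals), lengths(vals))))
  fit <- stats::aov(value ~ group, data = df)
  s <- summary(fit)[[1]]
  structure(list(f_stat = s[["F value"]][1],
                 df_between = s[["Df"]][1],
                 df_within = s[["Df"]][2],
                 p_value = s[["Pr(>F)"]][1],
                 fit = fit),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d,%d) = %.3f, p = %.4g\n",
              x$df_between, x$df_within, x$f_stat, x$p_value))
  invisible(x)
}

#' Tukey HSD post hoc comparisons
#'
#' All pairwise group comparisons with the studentized-range (Tukey HSD)
#' adjustment; the Tukey-Kramer form is used automatically for unequal
#' group sizes.
#'
#' @inheritParams one_way_anova
#' @param alpha family-wise significance level for the `significant`
#'   flag.
#' @return Tibble of class `tukey_table`: `group_a`, `group_b`,
#'   `mean_diff` (a minus b), `p_adj`, `significant`.
#' @export
tukey_hsd <- function(values, alpha = 0.05) {
  res <- one_way_anova(values)
  tk <- stats::TukeyHSD(res$fit)$group
  pair <- strsplit(rownames(tk), "-", fixed = TRUE)
  out <- tibble::tibble(
    group_a = vapply(pair, `[`, "", 1L),
    group_b = vapply(pair, `[`, "", 2L),
    mean_diff = tk[, "diff"],
    p_adj = tk[, "p adj"],
    significant = tk[, "p adj"] < alpha)
  attr(out, "alpha") <- alpha
  class(out) <- c("tukey_table", class(out))
  out
}

#' Pearson correlation between compartment measurements
#'
#' Product-moment correlation between paired per-image values — typically
#' the epithelium-only measurement against the complete-tissue
#' measurement of the same image — with a two-sided test.
#'
#' @param epithelium,complete paired numeric vectors (n >= 3).
#' @return List of class `pearson_result`: `r`, `p_value`, `n`.
#' @export
pearson_compartments <- function(epithelium, complete) {
  ok <- is.finite(epithelium) & is.finite(complete)
  x <- epithelium[ok]; y <- complete[ok]
  if (length(x) < 3L) stop("pearson_compartments needs at least 3 pairs")
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x)),
            class = "pearson_result")
}

#' @export
print.pearson_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (n = %d, p = %.4g)\n", x$r, x$n, x$p_value))
  invisible(x)
}

#' Fractal-dimension frequency analysis with interval narrowing
#'
#' Histograms the per-object (or per-image) boundary fractal dimensions
#' of each group and runs the one-way ANOVA twice: on the full filtered
#' data and on the values falling inside the narrow interval where the
#' frequency distributions concentrate (default \[1.05, 1.09\], endpoints
#' inclusive). Narrowing is a pure subset filter — no value is modified —
#' and typically sharpens group separation by discarding the heavy,
#' group-unspecific tails.
#'
#' @param fds_by_group named list of numeric FD vectors (already passed
#'   through the degenerate-value filter), or a `group`/`value` data
#'   frame.
#' @param bin_width histogram bin width (default 0.01).
#' @param narrow closed narrowing interval, low then high.
#' @return List of class `fd_frequency_result`: `histograms` (per group:
#'   `bin_edges`, `counts`), `full_anova`, `narrow_anova`,
#'   `narrow_interval`, `dropped_groups`.
#' @export
fd_frequency_analysis <- function(fds_by_group, bin_width = 0.01,
                                  narrow = c(1.05, 1.09)) {
  if (length(narrow) != 2L || narrow[1] > narrow[2])
    stop("narrow interval must be c(low, high) with low <= high")
  vals <- values_by_group(fds_by_group)
  rng <- range(unlist(vals))
  edges <- seq(floor(rng[1] / bin_width) * bin_width,
               ceiling(rng[2] / bin_width) * bin_width + bin_width / 2,
               by = bin_width)
  histograms <- lapply(vals, function(v) {
    h <- graphics::hist(v, breaks = edges, plot = FALSE, right = FALSE)
    list(bin_edges = h$breaks, counts = h$counts)
  })
  narrowed <- lapply(vals, function(v) v[v >= narrow[1] & v <= narrow[2]])
  empty <- names(narrowed)[lengths(narrowed) < 2L]
  if (length(empty)) {
    warning("group(s) dropped from narrowed ANOVA (fewer than 2 values ",
            "inside [", narrow[1], ", ", narrow[2], "]): ",
            paste(empty, collapse = ", "))
    narrowed <- narrowed[!names(narrowed) %in% empty]
  }
  full_anova <- one_way_anova(vals)
  narrow_anova <- if (length(narrowed) >= 2L) one_way_anova(narrowed) else NULL
  structure(list(histograms = histograms, full_anova = full_anova,
                 narrow_anova = narrow_anova, narrow_interval = narrow,
                 dropped_groups = empty),
            class = "fd_frequency_result")
}
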