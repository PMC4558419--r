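#' Default per-group synthetic cohort specifications
#'
#' The study-condition defaults encode the qualitative group structure
#' the pipeline is designed to detect: carcinoma groups (G2-G5) have
#' dots that are closer to circular (lower diameters ratio) with
#' smoother boundaries (lower ruggedness amplitude, hence lower
#' silhouette FD) and a disorganized architecture for high Gleason
#' patterns, while benign groups (BNH, AAH) have more elongated, more
#' rugged dots arranged in basal-band-wrapped glands. Dot counts rise
#' mildly with Gleason pattern without strong separation.
#'
#' @param ... overrides applied to every group's [synthetic_spec()]
#'   (e.g. `image_size`, `nuclei_per_image`, `noise_sd`).
#' @return Named list of six [synthetic_spec] objects.
#' @export
default_group_specs <- function(...) {
  base <- list(
    BNH = list(aspect_ratio_mean = 1.60, ruggedness_amplitude = 0.30,
               dots_per_nucleus_mean = 2.8, arrangement = "glandular"),
    AAH = list(aspect_ratio_mean = 1.55, ruggedness_amplitude = 0.28,
               dots_per_nucleus_mean = 2.6, arrangement = "glandular"),
    G2 = list(aspect_ratio_mean = 1.35, ruggedness_amplitude = 0.20,
              dots_per_nucleus_mean = 3.0, arrangement = "glandular"),
    G3 = list(aspect_ratio_mean = 1.33, ruggedness_amplitude = 0.16,
              dots_per_nucleus_mean = 3.0, arrangement = "disorganized"),
    G4 = list(aspect_ratio_mean = 1.32, ruggedness_amplitude = 0.14,
              dots_per_nucleus_mean = 3.2, arrangement = "disorganized"),
    G5 = list(aspect_ratio_mean = 1.30, ruggedness_amplitude = 0.12,
              dots_per_nucleus_mean = 3.4, arrangement = "disorganized"))
  overrides <- list(...)
  out <- lapply(names(base), function(g) {
    args <- c(list(group = g), base[[g]], overrides)
    do.call(synthetic_spec, args[!duplicated(names(args))])
  })
  names(out) <- names(base)
  out
}

#' Pipeline run configuration
#'
#' @param input either `list(type = "synthetic", specs_by_group = ...,
#'   images_per_group = n)` or `list(type = "directory", path = dir,
#'   labels = csv)` where the CSV maps `filename` to `patient_id` and
#'   `group`.
#' @param segmentation a [segmentation_config()].
#' @param prune_length_px skeleton pruning length (px).
#' @param narrow_interval closed FD narrowing interval.
#' @param bin_width FD histogram bin width.
#' @param alpha significance level for post hoc flags.
#' @param anova_unit `"image"` or `"patient"`: the averaging level fed to
#'   the ANOVA.
#' @param compute_skeleton_fd compute the per-image skeleton FD (set
#'   `FALSE` to skip the most expensive stage in large simulation
#'   studies that do not use it).
#' @param seed master seed; every random draw in a run derives from it.
#' @param output_dir optional directory for CSV/JSON/PNG artifacts.
#' @param write_skeletons write per-image skeleton masks as PNG.
#' @param verbose print per-stage progress.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input = list(type = "synthetic",
                                    specs_by_group = default_group_specs(),
                                    images_per_group = 5L),
                       segmentation = segmentation_config(),
                       prune_length_px = 5L,
                       narrow_interval = c(1.05, 1.09),
                       bin_width = 0.01,
                       alpha = 0.05,
                       anova_unit = c("image", "patient"),
                       compute_skeleton_fd = TRUE,
                       seed = 1L,
                       output_dir = NULL,
                       write_skeletons = FALSE,
                       verbose = FALSE) {
  structure(list(input = input, segmentation = segmentation,
                 prune_length_px = as.integer(prune_length_px),
                 narrow_interval = narrow_interval, bin_width = bin_width,
                 alpha = alpha, anova_unit = match.arg(anova_unit),
                 compute_skeleton_fd = isTRUE(compute_skeleton_fd),
                 seed = as.integer(seed), output_dir = output_dir,
                 write_skeletons = isTRUE(write_skeletons),
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Validate a pipeline configuration
#'
#' @param config a [run_config()] (or plain list with the same fields).
#' @return Character vector of violations, each naming the offending
#'   field; empty when the configuration is valid.
#' @export
validate_config <- function(config) {
  v <- character(0)
  inp <- config$input
  if (is.null(inp$type) || !inp$type %in% c("synthetic", "directory")) {
    v <- c(v, "input$type: must be 'synthetic' or 'directory'")
  } else if (inp$type == "synthetic") {
    missing <- setdiff(group_labels(), names(inp$specs_by_group))
    if (length(missing))
      v <- c(v, paste0("input$specs_by_group: missing group(s) ",
                       paste(missing, collapse = ", ")))
    for (g in intersect(names(inp$specs_by_group), group_labels())) {
      err <- tryCatch({validate_synthetic_spec(inp$specs_by_group[[g]]); NULL},
                      error = function(e) conditionMessage(e))
      if (!is.null(err)) v <- c(v, paste0("input$specs_by_group$", g, ": ", err))
    }
    if (is.null(inp$images_per_group) || inp$images_per_group < 1)
      v <- c(v, "input$images_per_group: must be >= 1")
  } else {
    if (is.null(inp$path) || !dir.exists(inp$path))
      v <- c(v, "input$path: directory does not exist")
    if (is.null(inp$labels) || !file.exists(inp$labels))
      v <- c(v, "input$labels: labels CSV not found")
  }
  if (length(config$narrow_interval) != 2L ||
      config$narrow_interval[1] > config$narrow_interval[2])
    v <- c(v, "narrow_interval: must be c(low, high) with low <= high")
  if (!is.numeric(config$alpha) || config$alpha <= 0 || config$alpha >= 1)
    v <- c(v, "alpha: must lie in (0, 1)")
  if (!is.numeric(config$seed) || length(config$seed) != 1L)
    v <- c(v, "seed: must be a single integer")
  cfgseg <- config$segmentation
  if (!inherits(cfgseg, "segmentation_config"))
    v <- c(v, "segmentation: must be a segmentation_config")
  if (config$prune_length_px < 0)
    v <- c(v, "prune_length_px: must be >= 0")
  v
}

# Small content hash (FNV-1a over the serialized object) used to stamp
# output artifacts with the configuration they came from.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full quantification pipeline
#'
#' Synthesizes (or loads) a labelled image cohort, segments AgNOR dots,
#' measures per-object morphometry and boundary FD, applies the
#' degenerate-value filter, computes per-image summaries including the
#' skeleton FD, and runs the statistics layer: six-group and pooled
#' (BNH / AAH / carcinoma) ANOVA with Tukey HSD for each metric,
#' epithelium-versus-complete Pearson correlations, and the narrowed
#' FD frequency analysis.
#'
#' @param config a [run_config()].
#' @return A list of class `run_result` with `objects` (per-object
#'   tibble), `images` (per-image tibble), `stats` (nested list),
#'   `report` (stage record counts, config echo + hash, timing) —
#'   plus CSV/JSON artifacts under `config$output_dir` when set.
#' @export
run_pipeline <- function(config = run_config()) {
  viol <- validate_config(config)
  if (length(viol))
    stop("invalid configuration:\n  ", paste(viol, collapse = "\n  "))
  t0 <- proc.time()[["elapsed"]]
  say <- function(...) if (config$verbose) message(sprintf(...))

  # --- stage 1: acquire ------------------------------------------------
  inp <- config$input
  if (inp$type == "synthetic") {
    say("simulating %d x 6 images", inp$images_per_group)
    cohort <- generate_cohort(inp$specs_by_group, inp$images_per_group,
                              seed = config$seed)
  } else {
    cohort <- load_cohort(inp$path, inp$labels)
  }
  if (!length(cohort)) stop("empty cohort: nothing to analyze")
  t_acq <- proc.time()[["elapsed"]]

  # --- stage 2: segment + measure -------------------------------------
  obj_list <- list(); img_list <- list()
  skipped <- 0L
  before_filter <- 0L
  for (k in seq_along(cohort)) {
    item <- cohort[[k]]
    res <- tryCatch({
      mask <- segment_agnor(item$image, config$segmentation)
      cmap <- if (!is.null(item$truth)) item$truth$nucleus_mask else NULL
      objs <- measure_objects(mask, pixel_size = item$image$pixel_size,
                              compartment_map = cmap,
                              config = config$segmentation)
      before_filter <- before_filter + nrow(objs)
      summ <- image_summary(objs, mask, item$image, nucleus_mask = cmap,
                            prune_length_px = config$prune_length_px,
                            group = item$group,
                            compute_skeleton = config$compute_skeleton_fd)
      kept <- filter_degenerate(objs)
      if (nrow(kept)) {
        kept$image_id <- item$image$image_id
        kept$patient_id <- item$patient_id
        kept$group <- item$group
      }
      summ$patient_id <- item$patient_id
      summ$image_kind <- item$image$kind
      if (config$write_skeletons && !is.null(config$output_dir) &&
          any(mask$pixels)) {
        sk <- skeletonize_prune(mask, config$prune_length_px)
        write_mask_png(sk$mask, file.path(config$output_dir,
          paste0(item$image$image_id, "_skeleton.png")))
      }
      list(objs = kept, summ = summ)
    }, error = function(e) {
      warning("image ", item$image$image_id, " skipped: ",
              conditionMessage(e))
      NULL
    })
    if (is.null(res)) { skipped <- skipped + 1L; next }
    obj_list[[length(obj_list) + 1L]] <- res$objs
    img_list[[length(img_list) + 1L]] <- res$summ
  }
  if (!length(img_list)) stop("all images failed segmentation")
  objects <- do.call(rbind, obj_list[lengths(obj_list) > 0 &
                                     vapply(obj_list, nrow, 1L) > 0])
  images <- do.call(rbind, img_list)
  t_meas <- proc.time()[["elapsed"]]
  say("measured %d images, %d objects after filtering", nrow(images),
      if (is.null(objects)) 0L else nrow(objects))

  # --- stage 3: statistics --------------------------------------------
  stats <- cohort_statistics(objects, images, config)
  t_stats <- proc.time()[["elapsed"]]

  report <- list(
    images_in = length(cohort),
    images_measured = nrow(images),
    images_skipped = skipped,
    objects_before_filter = before_filter,
    objects_after_filter = if (is.null(objects)) 0L else nrow(objects),
    seed = config$seed,
    config_hash = config_hash(config[setdiff(names(config),
                                             c("verbose", "output_dir"))]),
    package_version = as.character(utils::packageVersion("agnorfd")),
    seconds = c(acquire = t_acq - t0, measure = t_meas - t_acq,
                statistics = t_stats - t_meas))

  out <- structure(list(objects = objects, images = images, stats = stats,
                        report = report, config = config),
                   class = "run_result")
  if (!is.null(config$output_dir)) write_run_artifacts(out)
  out
}

#' Group-comparison statistics over measured cohort tables
#'
#' Runs the statistics layer on per-image (and optionally per-object)
#' measurement tables: for every metric a six-group one-way ANOVA with
#' Tukey HSD and the pooled comparison (BNH vs AAH vs carcinoma =
#' G2-G5), the narrowed FD frequency analysis over per-object boundary
#' FDs, and epithelium-versus-complete Pearson correlations when
#' compartments are available.
#'
#' @param objects per-object tibble with `boundary_fd`, `group`,
#'   `image_id`, `compartment` columns (or `NULL` to skip object-level
#'   analyses).
#' @param images per-image tibble as produced by [image_summary()] rows,
#'   with `patient_id` and `group`.
#' @param config a [run_config()] (supplies alpha, averaging unit, the
#'   narrow interval and bin width).
#' @return Nested list with `per_metric`, `fd_frequency`, `pearson`.
#' @export
cohort_statistics <- function(objects, images, config = run_config()) {
  metrics <- c("dot_count", "mean_dots_per_nucleus", "density_per_mm2",
               "total_normalized_area", "mean_roundness", "mean_object_fd",
               "skeleton_fd")
  unit_tab <- function(metric) {
    tab <- images[is.finite(images[[metric]]), c("patient_id", "group", metric)]
    if (config$anova_unit == "patient" && nrow(tab)) {
      tab <- stats::aggregate(tab[[metric]],
                              by = list(patient_id = tab$patient_id,
                                        group = tab$group), FUN = mean)
      names(tab)[3] <- metric
    }
    tab
  }
  per_metric <- lapply(metrics, function(metric) {
    tab <- unit_tab(metric)
    if (!nrow(tab)) return(NULL)
    by6 <- split(tab[[metric]], tab$group)
    by6 <- by6[lengths(by6) >= 2L]
    pooled <- ifelse(is_carcinoma(tab$group), "carcinoma", tab$group)
    by3 <- split(tab[[metric]], pooled)
    by3 <- by3[lengths(by3) >= 2L]
    safe <- function(expr) tryCatch(expr, error = function(e) NULL)
    list(
      group_means = vapply(split(tab[[metric]], tab$group), mean, 0),
      anova = if (length(by6) >= 2) safe(one_way_anova(by6)),
      tukey = if (length(by6) >= 2) safe(tukey_hsd(by6, config$alpha)),
      pooled_means = vapply(by3, mean, 0),
      pooled_anova = if (length(by3) >= 2) safe(one_way_anova(by3)),
      pooled_tukey = if (length(by3) >= 2) safe(tukey_hsd(by3, config$alpha)))
  })
  names(per_metric) <- metrics

  # narrowed-interval frequency analysis on per-object boundary FDs
  fd_freq <- NULL
  if (!is.null(objects) && nrow(objects)) {
    fds <- split(objects$boundary_fd, objects$group)
    fds <- fds[lengths(fds) >= 2L]
    if (length(fds) >= 2L)
      fd_freq <- withCallingHandlers(
        fd_frequency_analysis(fds, bin_width = config$bin_width,
                              narrow = config$narrow_interval),
        warning = function(w) invokeRestart("muffleWarning"))
  }

  # epithelium-versus-complete correlation of per-image dot counts
  pearson <- NULL
  if (!is.null(objects) && nrow(objects) &&
      any(objects$compartment != "unknown")) {
    cnt <- function(sel) {
      t <- table(factor(objects$image_id[sel],
                        levels = unique(images$image_id)))
      as.numeric(t)
    }
    all_n <- cnt(rep(TRUE, nrow(objects)))
    epi_n <- cnt(objects$compartment == "epithelium")
    str_n <- cnt(objects$compartment == "stroma")
    pearson <- list(
      epithelium_vs_complete = tryCatch(
        pearson_compartments(epi_n, all_n), error = function(e) NULL),
      stroma_vs_complete = tryCatch(
        pearson_compartments(str_n, all_n), error = function(e) NULL))
  }
  list(per_metric = per_metric, fd_frequency = fd_freq, pearson = pearson)
}

# ---- artifact I/O ----------------------------------------------------

#' Write a binary mask as an 8-bit PNG (0/255)
#' @param mask a [binary_mask].
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
write_mask_png <- function(mask, path) {
  m <- as_mask_matrix(mask)
  writeImage(Image(t(m) * 1), path, type = "png")
  invisible(path)
}

#' Write an RGB image as PNG or TIFF
#' @param image an [agnor_image].
#' @param path output path; extension selects the format (.png/.tif).
#' @return Invisibly, the path.
#' @export
write_rgb_image <- function(image, path) {
  px <- image$pixels / 255
  arr <- aperm(px, c(2, 1, 3))
  type <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "png"
  writeImage(Image(arr, colormode = "Color"), path, type = type)
  invisible(path)
}

#' Read an RGB image from disk
#' @param path PNG or TIFF file.
#' @param pixel_size micrometres per pixel to attach.
#' @param kind acquisition kind.
#' @return An [agnor_image].
#' @export
read_rgb_image <- function(path, pixel_size = 0.17, kind = "single") {
  img <- readImage(path)
  arr <- imageData(img)
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3), c(dim(arr), 3))
  px <- round(aperm(arr[, , 1:3, drop = FALSE], c(2, 1, 3)) * 255)
  storage.mode(px) <- "integer"
  agnor_image(px, pixel_size = pixel_size, kind = kind,
              image_id = sub("\\.[^.]+$", "", basename(path)))
}

# Load a directory cohort described by a labels CSV
# (columns: filename, patient_id, group [, pixel_size]).
load_cohort <- function(path, labels_csv) {
  lab <- utils::read.csv(labels_csv, stringsAsFactors = FALSE)
  need <- c("filename", "patient_id", "group")
  if (!all(need %in% names(lab)))
    stop("labels CSV must have columns: ", paste(need, collapse = ", "))
  out <- list()
  for (i in seq_len(nrow(lab))) {
    f <- file.path(path, lab$filename[i])
    img <- tryCatch(suppressWarnings(read_rgb_image(f,
             pixel_size = if ("pixel_size" %in% names(lab))
               lab$pixel_size[i] else 0.17)),
           error = function(e) {
             warning("unreadable image skipped: ", f); NULL
           })
    if (is.null(img)) next
    out[[length(out) + 1L]] <- list(image = img, truth = NULL,
                                    group = lab$group[i],
                                    patient_id = lab$patient_id[i])
  }
  out
}

write_run_artifacts <- function(result) {
  dir.create(result$config$output_dir, recursive = TRUE, showWarnings = FALSE)
  od <- result$config$output_dir
  hash <- result$report$config_hash
  if (!is.null(result$objects))
    utils::write.csv(cbind(result$objects, config_hash = hash),
                     file.path(od, "objects.csv"), row.names = FALSE)
  utils::write.csv(cbind(result$images, config_hash = hash),
                   file.path(od, "images.csv"), row.names = FALSE)
  jsonlite::write_json(stats_to_json(result$stats, result$report),
                       file.path(od, "statistics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(od)
}

# Strip non-serializable model fits before JSON export.
stats_to_json <- function(stats, report) {
  slim_anova <- function(a) if (is.null(a)) NULL else
    list(f_stat = a$f_stat, df_between = a$df_between,
         df_within = a$df_within, p_value = a$p_value)
  slim_tukey <- function(tk) if (is.null(tk)) NULL else
    as.data.frame(tk)
  per_metric <- lapply(stats$per_metric, function(m) {
    if (is.null(m)) return(NULL)
    list(group_means = as.list(m$group_means),
         anova = slim_anova(m$anova), tukey = slim_tukey(m$tukey),
         pooled_means = as.list(m$pooled_means),
         pooled_anova = slim_anova(m$pooled_anova),
         pooled_tukey = slim_tukey(m$pooled_tukey))
  })
  fdf <- stats$fd_frequency
  list(report = report,
       per_metric = per_metric,
       fd_frequency = if (!is.null(fdf)) list(
         narrow_interval = fdf$narrow_interval,
         full_anova = slim_anova(fdf$full_anova),
         narrow_anova = slim_anova(fdf$narrow_anova),
         dropped_groups = fdf$dropped_groups),
       pearson = lapply(stats$pearson, function(p) if (is.null(p)) NULL else
         list(r = p$r, p_value = p$p_value, n = p$n)))
}
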