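#' Analysis run configuration
#'
#' Bundles everything one control-or-enhanced analysis needs: the input
#' (a volume path or a [phantom_spec()]), the acquisition mode, a species
#' preset that fills the VOI edge and debris filter (apple/pear: 2400 um
#' VOI edge; tomato: 2000 um), stage parameters, the seed, and an output
#' directory. Explicit arguments override preset defaults. The resolved
#' configuration is serialized into the output directory for provenance.
#'
#' @param input path to a volume (TIFF) or a [phantom_spec()].
#' @param mode `"control"` or `"enhanced"`.
#' @param preset `"apple"`, `"pear"`, `"tomato"` or `"custom"`.
#' @param voi a [voi_spec()], or NULL to analyze the full volume (the
#'   minimum-volume rule applies only to explicit VOIs).
#' @param filter a [filter_spec()]; defaults to the preset's.
#' @param params named list of stage parameters: `class_count`,
#'   `min_component_voxels`, `opening_radius`, `watershed_h`,
#'   `edge_weight`, `recover_iterations`, `ridge_quantile`,
#'   `protect_opening_radius`, `protect_min_voxels`.
#' @param seed integer seed.
#' @param output_dir directory for artifacts, or NULL to skip writing.
#' @return an object of class `run_config`.
#' @export
run_config <- function(input, mode = c("control", "enhanced"),
                       preset = c("custom", "apple", "pear", "tomato"),
                       voi = NULL, filter = NULL, params = list(),
                       seed = 1L, output_dir = NULL) {
  mode <- match.arg(mode)
  preset <- match.arg(preset)
  if (is.null(filter) && preset != "custom")
    filter <- preset_filter(preset)
  if (is.null(filter)) filter <- filter_spec()
  if (is.null(voi) && preset != "custom") {
    edge <- if (preset == "tomato") 2000 else 2400
    voi <- list(edge = edge)  # resolved against the volume at run time
  }
  defaults <- list(class_count = NULL, min_component_voxels = 27L,
                   opening_radius = 1, watershed_h = 2, edge_weight = 1,
                   recover_iterations = 4L, ridge_quantile = 1,
                   protect_opening_radius = 2, protect_min_voxels = 64L)
  params <- utils::modifyList(defaults, params)
  structure(list(input = input, mode = mode, preset = preset, voi = voi,
                 filter = filter, params = params, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

#' Run the full segmentation and morphometry analysis
#'
#' Executes the stage chain: VOI extraction, intensity classification
#' (4 classes in enhanced mode — air, cell, flooded contrast, bright
#' boundary; 2 in control), despeckle/opening, Sobel edge map,
#' marker-controlled watershed, edge-constrained volume recovery with
#' all labels competing, border kill, morphometry, debris/geometry
#' filtering, dense-structure extraction (enhanced mode), and the VOI
#' summary. Recovery runs before border kill so that every label is
#' present to contest boundary voxels; the recovery growth mask is the
#' cell class plus thin bright material (boundaries), while compact
#' bright structures (vasculature, stone cells) are protected from
#' being claimed by cells. A stage-by-stage log of object counts is
#' kept and written with the artifacts.
#'
#' @param config a [run_config()].
#' @return list with `summary` (a `voi_summary`), `cells` (measured
#'   retained cells), `labels` (final [ctm_labels()]), `structures`,
#'   `log` (data frame), and `config`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  pr <- config$params
  log <- list()
  note <- function(stage, ...) {
    log[[length(log) + 1L]] <<- data.frame(stage = stage, ...,
                                           stringsAsFactors = FALSE)
  }

  volume <- if (inherits(config$input, "phantom_spec")) {
    spec <- config$input
    spec$random_seed <- config$seed
    spec$contrast_mode <- config$mode == "enhanced"
    generate_tissue(spec)$greyscale
  } else if (inherits(config$input, "ctm_volume")) {
    config$input
  } else {
    read_volume(config$input)
  }
  note("input", voxels = prod(dim(volume$data)))

  if (!is.null(config$voi)) {
    spec <- config$voi
    if (!inherits(spec, "voi_spec")) {
      d_um <- dim(volume$data) * volume$voxel_size
      edge <- min(spec$edge, d_um)
      origin <- pmax(1L, as.integer(round((d_um - edge) /
                                            (2 * volume$voxel_size))) + 1L)
      spec <- voi_spec(origin, rep(edge, 3))
    }
    volume <- tryCatch(extract_voi(volume, spec),
                       error = function(e)
                         stop("stage extract_voi: ", conditionMessage(e)))
    note("extract_voi", voxels = prod(dim(volume$data)))
  }
  if (volume$bit_depth > 8L) volume <- rescale_to_8bit(volume)
  vs <- volume$voxel_size
  voi_volume <- prod(dim(volume$data)) * vs^3

  if (!is.null(pr$class_count)) {
    classes <- classify_intensities(volume, pr$class_count)
  } else if (config$mode == "enhanced") {
    classes <- classify_enhanced(volume)
  } else {
    classes <- classify_intensities(volume, 2L)
  }
  class_count <- classes$n_classes
  note("classify", thresholds = paste(classes$thresholds, collapse = "/"))

  cell_mask <- classes$data == 1L
  clean <- morphological_clean(cell_mask, pr$min_component_voxels,
                               pr$opening_radius)
  note("clean", voxels = sum(clean))

  edges <- sobel_edge_magnitude(volume)
  labels <- watershed_separate(clean, edge_map = edges, h = pr$watershed_h,
                               edge_weight = pr$edge_weight,
                               voxel_size = vs)
  note("watershed", objects = max(labels$data))

  # growth mask: the cell class, plus thin bright boundary material; the
  # compact bright structures (opened components above the size cut,
  # away from the faces) stay off limits to cell growth
  grow_mask <- cell_mask
  if (class_count >= 3L) {
    bright_top <- classes$data == class_count - 1L
    protected <- morphological_clean(
      morphological_clean(bright_top, 0L, pr$protect_opening_radius),
      pr$protect_min_voxels, 0)
    shell <- array(FALSE, dim(protected))
    d <- dim(shell)
    shell[c(1, 2, d[1] - 1, d[1]), , ] <- TRUE
    shell[, c(1, 2, d[2] - 1, d[2]), ] <- TRUE
    shell[, , c(1, 2, d[3] - 1, d[3])] <- TRUE
    protected <- protected & !shell
    grow_mask <- grow_mask | (bright_top & !protected)
  }
  labels <- recover_volume(labels, grow_mask, edges,
                           pr$recover_iterations, pr$ridge_quantile)
  note("recover", voxels = sum(labels$data > 0))
  labels_all <- labels  # every segmented cell, incl. border objects

  labels <- border_kill(labels)
  note("border_kill", objects = sum(tabulate(labels$data) > 0))

  cells <- measure_labels(labels)
  borderkilled_cells <- cells

  cells <- apply_filters(cells, config$filter)
  note("filter", objects = nrow(cells))
  if (nrow(cells)) {
    map <- integer(max(labels$data))
    map[cells$label_id] <- cells$label_id
    labels <- ctm_labels(array(cpp_relabel(labels$data, map),
                               dim(labels$data)), vs)
  } else {
    labels <- ctm_labels(array(0L, dim(labels$data)), vs)
  }

  structures <- if (config$mode == "enhanced") {
    extract_dense_structures(classes, labels_all, vs)
  } else {
    list(labels = ctm_labels(array(0L, dim(labels$data)), vs),
         records = data.frame())
  }
  note("structures", objects = nrow(structures$records))

  summary <- summarize_voi(cells, structures$records, voi_volume,
                           borderkilled_cells = borderkilled_cells)
  log_df <- do.call(rbind, lapply(log, function(x) {
    data.frame(stage = x$stage, detail = paste(
      vapply(setdiff(names(x), "stage"),
             function(n) paste0(n, "=", x[[n]]), character(1)),
      collapse = " "), stringsAsFactors = FALSE)
  }))

  out <- list(summary = summary, cells = cells, labels = labels,
              structures = structures, log = log_df, config = config)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_volume(labels, file.path(config$output_dir, "labels.tif"))
    write_cell_table(cells, file.path(config$output_dir, "cells.csv"))
    jsonlite::write_json(unclass(summary),
                         file.path(config$output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    write.csv(log_df, file.path(config$output_dir, "stage_log.csv"),
              row.names = FALSE)
    jsonlite::write_json(serialize_config(config),
                         file.path(config$output_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

# Hierarchical classification for contrast-enhanced scans: a 3-class
# Otsu separates air / cell / bright robustly across porosities (a
# direct 4-class fit can split the dominant cell peak instead when the
# air fraction is small), then a second Otsu within the bright voxels
# separates flooded contrast from the brighter boundary/structure
# material. Result: 0 air, 1 cell, 2 flooded contrast, 3 bright.
classify_enhanced <- function(volume) {
  cl3 <- classify_intensities(volume, 3L)
  bright <- cl3$data == 2L
  vals <- as.integer(round(volume$data[bright]))
  if (!length(vals) || min(vals) == max(vals)) return(cl3)
  h <- tabulate(vals + 1L, nbins = 256L)
  tsub <- cpp_multiotsu(as.numeric(h), 2L)
  if (tsub <= cl3$thresholds[2]) return(cl3)
  cls <- cl3$data
  cls[bright & volume$data > tsub + 0.5] <- 3L
  structure(list(data = cls, thresholds = c(cl3$thresholds, tsub),
                 n_classes = 4L, voxel_size = volume$voxel_size),
            class = "ctm_classes")
}

# JSON-serializable view of a run_config (provenance record).
serialize_config <- function(config) {
  x <- unclass(config)
  if (inherits(x$input, "phantom_spec")) x$input <- unclass(x$input)
  if (inherits(x$input, "ctm_volume"))
    x$input <- paste0("<in-memory volume ",
                      paste(dim(x$input$data), collapse = "x"), ">")
  if (inherits(x$voi, "voi_spec")) x$voi <- unclass(x$voi)
  x$filter <- unclass(x$filter)
  x
}

#' Two-sample comparison of VOI summaries
#'
#' Independent two-sample t test (pooled-variance Student by default,
#' Welch by flag) on one summary field across replicate VOIs, plus the
#' percent increase of the enhanced group mean over the control group
#' mean. Significance is flagged at p < 0.05. The degenerate
#' zero-within-group-variance case is guarded: different means give
#' p = 0 (flagged significant), identical groups give t = 0, p = 1.
#'
#' @param control,enhanced lists of `voi_summary` objects (n >= 2 each).
#' @param field summary field name, e.g. `"filtered_cell_volume_pct"`.
#' @param var_equal pooled-variance Student t (TRUE, default) or Welch.
#' @return an object of class `group_comparison`.
#' @export
compare_groups <- function(control, enhanced, field, var_equal = TRUE) {
  pull <- function(g) vapply(g, function(s) as.numeric(s[[field]]),
                             numeric(1))
  x <- pull(control)
  y <- pull(enhanced)
  if (length(x) < 2L || length(y) < 2L)
    stop("need at least 2 replicates per group")
  n1 <- length(x); n2 <- length(y)
  m1 <- mean(x); m2 <- mean(y)
  if (var_equal) {
    sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- var(x) / n1; v2 <- var(y) / n2
    se <- sqrt(v1 + v2)
    df <- if (se > 0) (v1 + v2)^2 /
      (v1^2 / (n1 - 1) + v2^2 / (n2 - 1)) else n1 + n2 - 2
  }
  if (se == 0) {
    t_stat <- if (m1 == m2) 0 else sign(m2 - m1) * Inf
    p <- if (m1 == m2) 1 else 0
  } else {
    t_stat <- (m2 - m1) / se
    p <- 2 * pt(-abs(t_stat), df)
  }
  structure(list(
    field = field,
    control_mean = m1, control_sem = sd(x) / sqrt(n1),
    enhanced_mean = m2, enhanced_sem = sd(y) / sqrt(n2),
    pct_increase = if (m1 > 0) percent_increase(m1, m2) else NA_real_,
    t = t_stat, df = df, p_value = p,
    significant = p < 0.05), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> %s\n  control %.3f +/- %.3f, enhanced %.3f +/- %.3f\n",
    x$field, x$control_mean, x$control_sem, x$enhanced_mean,
    x$enhanced_sem))
  cat(sprintf("  %% increase %.2f, t = %.3f (df %.3g), p = %.4g%s\n",
              x$pct_increase, x$t, x$df, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}
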