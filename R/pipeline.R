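#' Two-tailed Fisher's exact test for a 2 x 2 table
#'
#' Exact two-sided p-value: with margins fixed, the hypergeometric
#' probabilities of all tables no more probable than the observed one are
#' summed (the convention of [stats::fisher.test()]; alternatives that
#' double one tail differ). Used for genotype-by-outcome counts such as
#' closure failure by genotype.
#'
#' @param table 2 x 2 integer matrix (rows = genotype, columns = outcome),
#'   or a length-4 vector `c(a, b, c, d)` filled by row.
#' @return Tibble: `p_value`, `odds_ratio`.
#' @export
fisher_exact_2x2 <- function(table) {
  if (is.vector(table) && length(table) == 4) {
    table <- matrix(table, 2, 2, byrow = TRUE)
  }
  if (!is.matrix(table) || !identical(dim(table), c(2L, 2L)) ||
      any(table < 0)) {
    abort("need a 2 x 2 table of non-negative counts")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("degenerate margins: empty row or column")
  }
  ht <- fisher.test(table)
  tibble(p_value = ht$p.value, odds_ratio = unname(ht$estimate))
}

#' Configure an end-to-end synthetic pipeline run
#'
#' Bundles the stage parameters for [run_pipeline()]: tessellation,
#' mosaic, render, classification, neighbour statistics, kinetics and
#' border analysis. One global seed drives every stage through
#' deterministic child streams.
#'
#' @param n_cells,domain_size,periodic,lattice_mode,lloyd_iterations
#'   Tessellation parameters (see [tessellation_spec()]).
#' @param p Recombination fraction.
#' @param border_width Border-exclusion strip in px (0 disables; periodic
#'   synthetic rasters have no boundary to exclude).
#' @param hi,lo,frac EGFP thresholds (see [classify_egfp()]).
#' @param dilation_radius Neighbour-graph dilation radius.
#' @param render A [render_spec()], or `NULL` for noise-free defaults.
#' @param dynamics A [dynamics_spec()] for the kinetics stage.
#' @param n_embryos_traces,cells_per_group Trace-cohort layout.
#' @param stages Character vector of enabled stages, a subset of
#'   `c("simulate", "features", "classify", "neighbours", "kinetics",
#'   "borders")`.
#' @param seed Global integer seed.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(n_cells = 400, domain_size = c(256, 256),
                            periodic = TRUE, lattice_mode = "voronoi",
                            lloyd_iterations = 2,
                            p = 0.16, border_width = 0,
                            hi = 0.08, lo = 0.06, frac = 0.75,
                            dilation_radius = 1,
                            render = NULL, dynamics = NULL,
                            n_embryos_traces = 5, cells_per_group = 8,
                            stages = c("simulate", "features", "classify",
                                       "neighbours", "kinetics", "borders"),
                            seed = 1L) {
  stopifnot_scalar_prob(p)
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(n_cells = n_cells, domain_size = domain_size,
                 periodic = periodic, lattice_mode = lattice_mode,
                 lloyd_iterations = lloyd_iterations, p = p,
                 border_width = border_width, hi = hi, lo = lo, frac = frac,
                 dilation_radius = dilation_radius,
                 render = render %||% render_spec(noise_sd = 0, psf_sigma = 0,
                                                  seed = seed),
                 dynamics = dynamics %||% dynamics_spec(seed = seed),
                 n_embryos_traces = n_embryos_traces,
                 cells_per_group = cells_per_group,
                 stages = stages, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the synthetic analysis pipeline end to end
#'
#' Executes the enabled stages in dependency order — simulate (tessellate,
#' rasterize, mosaic, render), features, classify (EGFP calls, neighbour
#' graph, cell classes), neighbours (Lewis fit and amplification summary),
#' kinetics (trace simulation, alignment, group comparison) and borders
#' (cap/cortex split) — writing per-stage CSVs, TIFF images, a metrics
#' JSON and a run log into `out_dir`. A stage whose inputs are missing
#' (because an upstream stage is disabled) raises an error.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with `metrics` (named list also written to
#'   `metrics.json`) and `paths`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("mosaictile_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "",
                                file = logf, append = TRUE)
  cat(sprintf("mosaictile pipeline | seed %d | %s\n", config$seed,
              paste(config$stages, collapse = " > ")), file = logf)
  metrics <- list(seed = config$seed)
  st <- function(s) s %in% config$stages
  need <- function(x, stage, from) {
    if (is.null(x)) abort(sprintf("stage '%s' needs output of stage '%s'", stage, from))
    x
  }
  tess <- ras <- mosaic <- channels <- feats <- calls <- graph <- classes <- NULL

  if (st("simulate")) {
    tess <- generate_tessellation(tessellation_spec(
      config$n_cells, config$domain_size, config$periodic,
      config$lloyd_iterations, config$lattice_mode,
      seed = child_seed(config$seed, 1L)))
    ras <- rasterize_labels(tess)
    mosaic <- assign_mosaic(tess, config$p, seed = child_seed(config$seed, 2L))
    channels <- render_channels(ras$labels, mosaic, config$render)
    write_label_tiff(ras$labels, file.path(out_dir, "labels.tif"))
    write_channel_tiff(channels$tdtom, file.path(out_dir, "tdtom.tif"))
    write_channel_tiff(channels$egfp, file.path(out_dir, "egfp.tif"))
    readr::write_csv(mutate(ras$truth,
                            recombined = mosaic$recombined[.data$orig_id]),
                     file.path(out_dir, "truth.csv"))
    metrics$n_cells <- nrow(ras$truth)
    metrics$mean_true_degree <- mean(ras$truth$true_degree)
    log_line("simulate: %d cells, mean true degree %.3f",
             nrow(ras$truth), metrics$mean_true_degree)
  }

  labels <- NULL
  if (!is.null(ras)) {
    excl <- exclude_border_cells(ras$labels, config$border_width)
    labels <- excl$labels
    metrics$n_border_excluded <- length(excl$excluded)
  }

  if (st("features")) {
    feats <- compute_cell_features(need(labels, "features", "simulate"))
    readr::write_csv(feats, file.path(out_dir, "features.csv"))
    log_line("features: %d cells", nrow(feats))
  }

  if (st("classify")) {
    egfp <- rescale_unit_interval(need(channels, "classify", "simulate")$egfp)
    calls <- classify_egfp(labels, egfp, config$hi, config$lo, config$frac)
    graph <- build_neighbour_graph(labels, config$dilation_radius,
                                   periodic = config$periodic)
    classes <- assign_cell_classes(graph, calls)
    readr::write_csv(calls, file.path(out_dir, "egfp_calls.csv"))
    readr::write_csv(as_tibble(graph), file.path(out_dir, "edges.csv"))
    readr::write_csv(classes, file.path(out_dir, "classes.csv"))
    truth_rec <- mosaic$recombined[ras$truth$orig_id][match(calls$cell_id, ras$truth$cell_id)]
    confusion <- sum((calls$call == "EGFP_POS") != truth_rec |
                       calls$call == "UNCLASSIFIED")
    metrics$classification_confusion <- confusion
    metrics$mean_graph_degree <- mean(graph_degrees(graph)$degree)
    log_line("classify: confusion vs truth = %d, mean graph degree %.3f",
             confusion, metrics$mean_graph_degree)
  }

  if (st("neighbours")) {
    need(classes, "neighbours", "classify")
    amp <- neighbour_count_summary(graph, classes)
    lw <- lewis_law_fit(rename(ras$truth, area = "true_area_px2"), graph)
    metrics$amplification <- as.list(amp)
    metrics$lewis <- list(slope = lw$slope, intercept = lw$intercept,
                          pearson_r = lw$pearson_r, p_value = lw$p_value,
                          n_cells = lw$n_cells)
    readr::write_csv(amp, file.path(out_dir, "amplification.csv"))
    log_line("neighbours: p_hat %.3f, fraction neighbouring %.3f",
             amp$p_hat, amp$fraction_replete_neighbouring)
  }

  if (st("kinetics")) {
    cohort <- make_trace_cohort(config$n_embryos_traces, config$cells_per_group)
    dyn <- config$dynamics
    dyn$seed <- child_seed(config$seed, 3L)
    traces <- simulate_area_traces(cohort, dyn)
    aligned <- align_at_max(traces)
    gm <- group_mean_trace(aligned)
    cmp <- compare_groups_per_timepoint(aligned, "neighbour", "control")
    readr::write_csv(select(aligned, -"peak_t"), file.path(out_dir, "aligned_traces.csv"))
    readr::write_csv(gm, file.path(out_dir, "group_mean_traces.csv"))
    readr::write_csv(cmp, file.path(out_dir, "neighbour_vs_control.csv"))
    metrics$kinetics <- list(
      n_traces = dplyr::n_distinct(traces$cell_id),
      n_sig_timepoints_neighbour_vs_control = sum(cmp$p_adjusted < 0.05))
    log_line("kinetics: %d traces, %d significant timepoints (neighbour vs control)",
             metrics$kinetics$n_traces,
             metrics$kinetics$n_sig_timepoints_neighbour_vs_control)
  }

  if (st("borders")) {
    need(classes, "borders", "classify")
    segs <- extract_border_segments(labels, graph, config$dilation_radius)
    bsum <- border_intensity_summary(segs, channels$tdtom, classes)
    readr::write_csv(bsum, file.path(out_dir, "border_summary.csv"))
    metrics$borders <- list(n_segments = nrow(segs))
    log_line("borders: %d segments", nrow(segs))
  }

  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  writeLines(write_report(metrics), file.path(out_dir, "report.txt"))
  invisible(list(metrics = metrics, paths = list(out_dir = out_dir)))
}

#' Format a pipeline metrics list as a human-readable report
#'
#' @param metrics Metrics list as produced by [run_pipeline()] (or read
#'   back from its `metrics.json`).
#' @return Character vector of report lines.
#' @export
write_report <- function(metrics) {
  if (is.null(metrics) || length(metrics) == 0) abort("empty metrics")
  ln <- c("mosaictile run report",
          sprintf("  seed: %s", metrics$seed %||% "?"))
  if (!is.null(metrics$n_cells)) {
    ln <- c(ln, sprintf("  cells: %d (mean true degree %.3f)",
                        metrics$n_cells, metrics$mean_true_degree))
  }
  if (!is.null(metrics$classification_confusion)) {
    ln <- c(ln, sprintf("  EGFP classification confusion vs truth: %d cells",
                        metrics$classification_confusion),
            sprintf("  mean neighbour-graph degree: %.3f",
                    metrics$mean_graph_degree))
  }
  if (!is.null(metrics$amplification)) {
    a <- metrics$amplification
    ln <- c(ln,
            sprintf("  recombination fraction (p_hat): %.3f", a$p_hat),
            sprintf("  neighbours of deleted cells: %.2f total / %.2f replete",
                    a$mean_total_neighbours_of_deleted,
                    a$mean_replete_neighbours_of_deleted),
            sprintf("  fraction of replete cells neighbouring deleted: %.3f",
                    a$fraction_replete_neighbouring),
            sprintf("  unique replete neighbours per deleted cell: %.2f",
                    a$unique_neighbours_per_deleted))
  }
  if (!is.null(metrics$lewis)) {
    ln <- c(ln, sprintf("  Lewis' law: area = %.1f + %.1f x N, r = %.3f (p = %.3g, n = %d)",
                        metrics$lewis$intercept, metrics$lewis$slope,
                        metrics$lewis$pearson_r, metrics$lewis$p_value,
                        metrics$lewis$n_cells))
  }
  if (!is.null(metrics$kinetics)) {
    ln <- c(ln, sprintf("  kinetics: %d traces, %d Bonferroni-significant timepoints (neighbour vs control)",
                        metrics$kinetics$n_traces,
                        metrics$kinetics$n_sig_timepoints_neighbour_vs_control))
  }
  if (!is.null(metrics$borders)) {
    ln <- c(ln, sprintf("  border segments: %d", metrics$borders$n_segments))
  }
  ln
}
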