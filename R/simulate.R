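#' Specify apical-area pulse dynamics
#'
#' Parameters of the class-dependent apical-area model used to emulate
#' live-imaged constriction behaviour at 1-minute sampling over a short
#' (default 20-minute) window. Each cell performs a single dilation ramp up
#' to a randomly timed peak followed by a constriction decay — one peak per
#' window suffices because the analysis aligns every cell at its largest
#' observed area. Rates are per-class means with lognormal cell-to-cell
#' variation; phases are asynchronous by construction (uniform peak times).
#'
#' Class defaults encode the studied phenotype: deleted cells dilate twice
#' as fast as distant/control cells but constrict normally; neighbour cells
#' dilate normally but do not constrict; control and distant cells do both
#' normally. The magnitude of the faster dilation is a free parameter of
#' the generator (2x by default).
#'
#' @param n_timepoints Number of 1-minute frames (default 20, >= 3).
#' @param baseline_area Peak apical area in px^2 (default 300).
#' @param dilation_rate Named per-class pre-peak rates (fraction/min).
#' @param constriction_rate Named per-class post-peak rates (fraction/min).
#' @param rate_cv Lognormal coefficient of variation of per-cell rates.
#' @param noise_sd Multiplicative measurement noise SD (fraction).
#' @param seed Integer seed.
#' @return A list of class `"dynamics_spec"`.
#' @export
dynamics_spec <- function(n_timepoints = 20,
                          baseline_area = 300,
                          dilation_rate = c(control = 0.015, deleted = 0.030,
                                            neighbour = 0.015, distant = 0.015),
                          constriction_rate = c(control = 0.020, deleted = 0.020,
                                                neighbour = 0.000, distant = 0.020),
                          rate_cv = 0.2,
                          noise_sd = 0.05,
                          seed = 1L) {
  if (n_timepoints < 3) abort("`n_timepoints` must be >= 3")
  if (any(dilation_rate < 0) || any(constriction_rate < 0)) {
    abort("rates must be >= 0")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  structure(list(n_timepoints = as.integer(n_timepoints),
                 baseline_area = baseline_area,
                 dilation_rate = dilation_rate,
                 constriction_rate = constriction_rate,
                 rate_cv = rate_cv, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "dynamics_spec")
}

#' Simulate per-cell apical-area time series
#'
#' @param cells Tibble with `cell_id`, `group` (one of the classes named in
#'   the spec's rate vectors) and optionally `embryo_id`; see
#'   [make_trace_cohort()] for a convenience constructor.
#' @param spec A [dynamics_spec()].
#' @return Long tibble: `cell_id`, `embryo_id`, `group`, `t_min`,
#'   `area_px2`, plus `peak_t` (the true peak time, ground truth for
#'   alignment checks).
#' @export
simulate_area_traces <- function(cells, spec) {
  stopifnot(inherits(spec, "dynamics_spec"))
  grp <- as.character(cells$group)
  bad <- setdiff(unique(grp), names(spec$dilation_rate))
  if (length(bad)) abort(paste("no rates for class:", paste(bad, collapse = ", ")))
  nt <- spec$n_timepoints
  tt <- 0:(nt - 1)
  nc <- nrow(cells)
  with_seed(spec$seed, {
    # interior peak times so every cell shows both a dilation and a
    # constriction phase within the window
    peak <- sample(1:(nt - 2), nc, replace = TRUE)
    jit <- function(mu) mu * exp(rnorm(nc, 0, spec$rate_cv) - spec$rate_cv^2 / 2)
    d <- jit(spec$dilation_rate[grp])
    cns <- jit(spec$constriction_rate[grp])
    traces <- purrr::map(seq_len(nc), function(i) {
      rel <- ifelse(tt <= peak[i],
                    1 - d[i] * (peak[i] - tt),
                    1 - cns[i] * (tt - peak[i]))
      rel <- pmax(rel, 0.1)
      a <- spec$baseline_area * rel
      if (spec$noise_sd > 0) a <- a * (1 + rnorm(nt, 0, spec$noise_sd))
      pmax(a, 1)
    })
    tibble(cell_id = rep(cells$cell_id, each = nt),
           embryo_id = rep(cells$embryo_id %||% 1L, each = nt),
           group = rep(grp, each = nt),
           t_min = rep(tt, times = nc),
           area_px2 = unlist(traces),
           peak_t = rep(peak, each = nt))
  })
}

#' Lay out a cell cohort for trace simulation
#'
#' @param n_embryos Embryos per group set.
#' @param cells_per_group Cells of each group per embryo.
#' @param groups Character vector of class names.
#' @return Tibble: `cell_id`, `embryo_id`, `group`.
#' @export
make_trace_cohort <- function(n_embryos = 5, cells_per_group = 8,
                              groups = c("control", "deleted", "neighbour", "distant")) {
  d <- tidyr::expand_grid(embryo_id = seq_len(n_embryos),
                          group = groups,
                          rep = seq_len(cells_per_group))
  mutate(select(d, -"rep"), cell_id = dplyr::row_number(), .before = 1)
}

#' Simulate a hierarchical laser-ablation cohort
#'
#' Draws per-cell post-ablation retraction (% area change, negative =
#' retraction) hierarchically: a shared embryo effect
#' `~ Normal(0, sigma_embryo)` plus per-cell noise
#' `~ Normal(class mean + embryo effect, sigma_cell)`. Pre/post areas are
#' emitted consistently with the drawn percentage so that
#' [retraction_percent()] recovers it exactly.
#'
#' @param class_means Named vector of mean retraction (%) per cell type
#'   (e.g. `c(control = -20, EGFP = -20, neighbour = -2, distant = -20)`).
#' @param n_embryos Embryos (each contributes every cell type).
#' @param cells_per_type Cells per embryo and type.
#' @param sigma_embryo,sigma_cell Between-embryo and within-embryo SDs (%).
#' @param pre_area_mean,pre_area_sd Pre-ablation area distribution (um^2).
#' @param seed Integer seed.
#' @return Tibble: `embryo_id`, `unit`, `cell_type`, `pre_area`,
#'   `post_area`, `true_retraction_pct`.
#' @export
simulate_ablation_cohort <- function(class_means = c(control = -20, EGFP = -20,
                                                     neighbour = -2, distant = -20),
                                     n_embryos = 10, cells_per_type = 3,
                                     sigma_embryo = 4, sigma_cell = 6,
                                     pre_area_mean = 60, pre_area_sd = 10,
                                     seed = 1L) {
  with_seed(seed, {
    d <- tidyr::expand_grid(embryo_id = seq_len(n_embryos),
                            cell_type = names(class_means),
                            rep = seq_len(cells_per_type))
    emb_eff <- rnorm(n_embryos, 0, sigma_embryo)
    retr <- unname(class_means[d$cell_type]) + emb_eff[d$embryo_id] +
      rnorm(nrow(d), 0, sigma_cell)
    retr <- pmax(retr, -95)
    pre <- pmax(rnorm(nrow(d), pre_area_mean, pre_area_sd), 5)
    tibble(embryo_id = d$embryo_id, unit = "cell",
           cell_type = d$cell_type,
           pre_area = pre,
           post_area = pre * (1 + retr / 100),
           true_retraction_pct = unname(retr))
  })
}

#' Specify a synthetic embryo cohort
#'
#' @param n_embryos Number of embryos (>= 3).
#' @param p_range Recombination-fraction range (uniform draw per embryo).
#' @param eversion_intercept Eversion (um) at neighbour fraction 0
#'   (positive = elevated folds).
#' @param eversion_slope Change in eversion per unit neighbour fraction
#'   (um; negative values mean more neighbour-class cells push the folds
#'   towards eversion).
#' @param eversion_noise_sd Embryo-level noise SD (um).
#' @param lattice_cells,lattice_px Size of the per-embryo hexagonal lattice
#'   used to realise the mosaic.
#' @param seed Integer seed.
#' @return A list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_embryos = 7, p_range = c(0.05, 0.35),
                        eversion_intercept = 30, eversion_slope = -150,
                        eversion_noise_sd = 15,
                        lattice_cells = 900, lattice_px = c(128, 128),
                        seed = 1L) {
  if (n_embryos < 3) abort("`n_embryos` must be >= 3")
  stopifnot_scalar_prob(p_range, "p_range")
  structure(list(n_embryos = as.integer(n_embryos), p_range = p_range,
                 eversion_intercept = eversion_intercept,
                 eversion_slope = eversion_slope,
                 eversion_noise_sd = eversion_noise_sd,
                 lattice_cells = as.integer(lattice_cells),
                 lattice_px = lattice_px,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate an embryo cohort linking mosaicism to neural fold eversion
#'
#' Per embryo: draws a recombination fraction `p ~ Uniform(p_range)`,
#' realises a Bernoulli mosaic on a periodic hexagonal lattice, computes
#' the fraction of replete cells that neighbour a deleted cell from the
#' true adjacency graph, and sets
#' `eversion = intercept + slope * neighbour_fraction + noise`.
#'
#' @param spec A [cohort_spec()].
#' @return Tibble: `embryo_id`, `p`, `p_hat`, `neighbour_fraction`,
#'   `unique_neighbours_per_deleted`, `eversion_um`.
#' @export
simulate_embryo_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  tess <- generate_tessellation(
    tessellation_spec(spec$lattice_cells, spec$lattice_px, periodic = TRUE,
                      lattice_mode = "hexagonal", seed = spec$seed))
  graph <- structure(tess$edges, nodes = tess$cells$cell_id,
                     class = c("neighbour_graph", class(tess$edges)))
  ps <- with_seed(child_seed(spec$seed, 1L),
                  runif(spec$n_embryos, spec$p_range[1], spec$p_range[2]))
  noise <- with_seed(child_seed(spec$seed, 2L),
                     rnorm(spec$n_embryos, 0, spec$eversion_noise_sd))
  rows <- purrr::map(seq_len(spec$n_embryos), function(e) {
    mos <- assign_mosaic(tess, ps[e], seed = child_seed(spec$seed, 2L + e))
    calls <- tibble(cell_id = mos$cell_id,
                    call = factor(ifelse(mos$recombined, "EGFP_POS", "EGFP_NEG"),
                                  levels = c("EGFP_POS", "EGFP_NEG", "UNCLASSIFIED")))
    cls <- assign_cell_classes(graph, calls)
    n_del <- sum(cls$class == "DELETED")
    n_nei <- sum(cls$class == "NEIGHBOUR")
    n_dis <- sum(cls$class == "DISTANT")
    nf <- if (n_nei + n_dis > 0) n_nei / (n_nei + n_dis) else NA_real_
    tibble(embryo_id = e, p = ps[e],
           p_hat = mean(mos$recombined),
           neighbour_fraction = nf,
           unique_neighbours_per_deleted = if (n_del > 0) n_nei / n_del else NA_real_)
  })
  out <- bind_rows(rows)
  mutate(out, eversion_um = spec$eversion_intercept +
           spec$eversion_slope * .data$neighbour_fraction + noise)
}
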