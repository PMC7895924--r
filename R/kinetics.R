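#' Align apical-area traces at their maximum
#'
#' Pulsatile cells can be in dilation or constriction phase at the start of
#' a short imaging window, so traces are synchronised by placing `T = 0` at
#' each cell's largest observed apical area (ties broken by the earliest
#' occurrence) and expressing areas as a percentage of that maximum.
#' Negative aligned times are the dilation phase, positive times the
#' constriction phase.
#'
#' @param traces Long tibble with `cell_id`, `t_min`, `area_px2` and
#'   optionally `embryo_id`, `group` (carried through). Areas must be
#'   positive; the per-cell time grid must be complete at 1-min spacing.
#' @return Long tibble adding `aligned_t` and `norm_area` (100 at `T = 0`);
#'   per cell, `max(norm_area)` is exactly 100 and the multiset of raw
#'   areas is unchanged. Cells with fewer than 5 timepoints on either side
#'   of the peak are flagged in `short_side`.
#' @export
align_at_max <- function(traces) {
  if (any(traces$area_px2 <= 0)) abort("areas must be positive")
  out <- mutate(group_by(traces, .data$cell_id),
                aligned_t = .data$t_min - .data$t_min[which.max(.data$area_px2)],
                norm_area = 100 * .data$area_px2 / max(.data$area_px2),
                short_side = min(max(-.data$aligned_t), max(.data$aligned_t)) < 5)
  ungroup(out)
}

#' Group mean trace with SEM
#'
#' Averages aligned, normalised traces across the cells of each group at
#' every aligned timepoint, reporting mean, SEM (`sd / sqrt(n)`) and the
#' number of contributing cells. Timepoints carried by a single cell have
#' no SEM and are flagged.
#'
#' @param aligned Tibble from [align_at_max()] with a `group` column.
#' @param value Column to average (default `norm_area`; use `area_px2` for
#'   raw-area mode).
#' @return Tibble: `group`, `aligned_t`, `mean`, `sem`, `n`, `single_cell`.
#' @export
group_mean_trace <- function(aligned, value = "norm_area") {
  if (nrow(aligned) == 0) abort("empty trace set")
  v <- rlang::sym(value)
  out <- summarise(group_by(aligned, .data$group, .data$aligned_t),
                   mean = mean(!!v),
                   sem = sd(!!v) / sqrt(dplyr::n()),
                   n = dplyr::n(), .groups = "drop")
  mutate(out, single_cell = .data$n < 2)
}

#' Per-timepoint group comparison with embryo-level aggregation
#'
#' At each aligned timepoint, cell values are first averaged within embryo
#' (the embryo is the unit of measure, protecting against
#' pseudoreplication of cells from the same embryo), the two groups are
#' compared by a Welch two-sample t-test across embryo means, and p-values
#' are Bonferroni-multiplied by the number of tested timepoints (capped at
#' 1). Only timepoints where both groups retain at least two embryos are
#' tested.
#'
#' @param aligned Tibble from [align_at_max()] with `group` and
#'   `embryo_id` columns.
#' @param group_a,group_b The two group labels to compare.
#' @param value Column to compare (default `norm_area`).
#' @return Tibble: `aligned_t`, `mean_a`, `mean_b`, `n_embryos_a`,
#'   `n_embryos_b`, `p_value`, `p_adjusted`.
#' @export
compare_groups_per_timepoint <- function(aligned, group_a, group_b,
                                         value = "norm_area") {
  v <- rlang::sym(value)
  d <- filter(aligned, .data$group %in% c(group_a, group_b))
  if (dplyr::n_distinct(d$embryo_id[d$group == group_a]) < 2 ||
      dplyr::n_distinct(d$embryo_id[d$group == group_b]) < 2) {
    abort("need >= 2 embryos per group")
  }
  emb <- summarise(group_by(d, .data$group, .data$embryo_id, .data$aligned_t),
                   value = mean(!!v), .groups = "drop")
  wide <- tidyr::pivot_wider(
    summarise(group_by(emb, .data$aligned_t, .data$group),
              vals = list(.data$value), .groups = "drop"),
    names_from = "group", values_from = "vals")
  va <- wide[[group_a]]; vb <- wide[[group_b]]
  ok <- purrr::map_lgl(va, ~ length(.x) >= 2) &
    purrr::map_lgl(vb, ~ length(.x) >= 2)
  wide <- wide[ok, ]; va <- va[ok]; vb <- vb[ok]
  m <- nrow(wide)
  p <- purrr::map2_dbl(va, vb, function(x, y) {
    if (sd(c(x, y)) == 0) return(1)
    suppressWarnings(t.test(x, y)$p.value)
  })
  tibble(aligned_t = wide$aligned_t,
         mean_a = purrr::map_dbl(va, mean),
         mean_b = purrr::map_dbl(vb, mean),
         n_embryos_a = lengths(va), n_embryos_b = lengths(vb),
         p_value = p,
         p_adjusted = pmin(1, p * m))
}

#' Percentage area change after ablation
#'
#' `100 * (post - pre) / pre`: negative values are retraction (area loss
#' when a cell or cluster is released from surrounding tension), positive
#' values dilation. Scale-invariant, so px^2 and um^2 inputs agree.
#'
#' @param records Tibble with `pre_area`, `post_area` (> 0).
#' @return The input with a `retraction_pct` column.
#' @export
retraction_percent <- function(records) {
  if (any(records$pre_area <= 0)) abort("`pre_area` must be positive")
  mutate(records, retraction_pct =
           100 * (.data$post_area - .data$pre_area) / .data$pre_area)
}

#' Average retraction per embryo and cell type
#'
#' Averages per-cell retraction within each embryo and cell type so the
#' embryo, not the cell, is the unit of measure for downstream ANOVA or
#' t-tests; pooling raw cells would inflate type-I error through
#' pseudoreplication.
#'
#' @param records Tibble with `embryo_id`, `cell_type` and
#'   `retraction_pct` (see [retraction_percent()]).
#' @return Tibble: `embryo_id`, `cell_type`, `n_cells`, `retraction_pct`.
#' @export
embryo_level_average <- function(records) {
  summarise(group_by(records, .data$embryo_id, .data$cell_type),
            n_cells = dplyr::n(),
            retraction_pct = mean(.data$retraction_pct),
            .groups = "drop")
}

#' Sample size for a two-group comparison of area reduction
#'
#' Smallest integer n per group such that a two-sample t-test at
#' significance `alpha` reaches the target power for a true difference
#' `delta` with common SD `sd` (exact noncentral-t power via
#' [stats::power.t.test()], which refines the normal approximation
#' `n ~ 2 (z_{1-a/2} + z_{1-b})^2 (sd/delta)^2`). The minimum returned is
#' 2, the smallest group size a t-test admits.
#'
#' @param delta True difference to detect (e.g. percentage points of area
#'   reduction).
#' @param sd Common standard deviation, same units as `delta`.
#' @param alpha Two-sided significance level (default 0.05).
#' @param power Target power (default 0.8).
#' @return Integer n per group.
#' @export
sample_size_two_group <- function(delta, sd, alpha = 0.05, power = 0.8) {
  if (delta <= 0 || sd <= 0) abort("`delta` and `sd` must be positive")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    abort("`alpha` and `power` must lie in (0, 1)")
  }
  # power at the minimum n; below-floor targets return the floor
  p2 <- power.t.test(n = 2, delta = delta, sd = sd, sig.level = alpha)$power
  if (p2 >= power) return(2L)
  n <- ceiling(power.t.test(delta = delta, sd = sd, sig.level = alpha,
                            power = power)$n - 1e-9)
  # ceiling of the continuous solution is the smallest integer n, since
  # power is increasing in n; guard against boundary rounding
  while (power.t.test(n = n, delta = delta, sd = sd,
                      sig.level = alpha)$power < power) {
    n <- n + 1L
  }
  as.integer(n)
}
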