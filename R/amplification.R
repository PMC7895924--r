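#' Fit Lewis' law: apical area against neighbour number
#'
#' Lewis' law is the empirical linear relation between an epithelial cell's
#' apical area and its number of neighbours. Fits ordinary least squares of
#' area on degree and reports the Pearson correlation with its two-tailed
#' p-value.
#'
#' @param features Tibble with `cell_id` and `area` (e.g. from
#'   [compute_cell_features()] or a tessellation truth table with area in
#'   an `area` column).
#' @param graph A `"neighbour_graph"`.
#' @param classes Optional [assign_cell_classes()] tibble; with `subset`
#'   restricts the fit to one cell class (e.g. `"DELETED"`, the
#'   deleted-cell-centric fit).
#' @param subset Optional class name to filter on.
#' @return Object of class `"lewis_fit"` with elements `slope`,
#'   `intercept`, `pearson_r`, `p_value`, `n_cells`, `model` (the `lm`
#'   fit) and `data`.
#' @export
lewis_law_fit <- function(features, graph, classes = NULL, subset = NULL) {
  d <- inner_join(select(features, "cell_id", "area"), graph_degrees(graph),
                  by = "cell_id")
  if (!is.null(subset)) {
    if (is.null(classes)) abort("`subset` requires `classes`")
    keep <- classes$cell_id[as.character(classes$class) == subset]
    d <- filter(d, .data$cell_id %in% keep)
  }
  if (nrow(d) < 3) abort("need >= 3 cells for a Lewis'-law fit")
  if (stats::var(d$degree) == 0) abort("zero variance in neighbour number")
  fit <- lm(area ~ degree, data = d)
  ct <- cor.test(d$degree, d$area, method = "pearson")
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 pearson_r = unname(ct$estimate),
                 p_value = ct$p.value,
                 n_cells = nrow(d),
                 model = fit, data = d),
            class = "lewis_fit")
}

#' @export
print.lewis_fit <- function(x, ...) {
  cat(sprintf("<lewis_fit> n = %d cells: area = %.3f + %.3f x neighbours, r = %.3f (p = %.3g)\n",
              x$n_cells, x$intercept, x$slope, x$pearson_r, x$p_value))
  invisible(x)
}

#' Neighbour-count summary of the mosaic
#'
#' Deleted-cell-centric neighbour statistics: for every deleted cell, its
#' total neighbour count and its replete (EGFP-negative) neighbour count,
#' averaged over deleted cells; plus the observed recombination fraction,
#' the fraction of replete cells neighbouring a deleted cell, and the
#' unique-neighbour ratio. Deleted-deleted contacts count toward total
#' degree but never toward replete counts. Unclassified cells are excluded
#' from every count and denominator.
#'
#' @param graph A `"neighbour_graph"`.
#' @param classes Tibble from [assign_cell_classes()].
#' @return One-row tibble: `p_hat`, `mean_total_neighbours_of_deleted`,
#'   `mean_replete_neighbours_of_deleted`, `fraction_replete_neighbouring`,
#'   `unique_neighbours_per_deleted`, `n_deleted`, `n_replete`. The
#'   deleted-centric fields are `NA` (with a warning) when no cell is
#'   deleted.
#' @export
neighbour_count_summary <- function(graph, classes) {
  cls <- setNames(as.character(classes$class), classes$cell_id)
  n_del <- sum(cls == "DELETED")
  n_nei <- sum(cls == "NEIGHBOUR")
  n_dis <- sum(cls == "DISTANT")
  p_hat <- if (n_del + n_nei + n_dis > 0) n_del / (n_del + n_nei + n_dis) else NA_real_
  if (n_del == 0) {
    warn("no deleted cells: deleted-centric summaries undefined")
    tot <- rep_mean <- NA_real_
  } else {
    del_ids <- names(cls)[cls == "DELETED"]
    ends <- c(graph$a, graph$b)
    other <- c(graph$b, graph$a)
    sel <- as.character(ends) %in% del_ids
    cl_other <- cls[as.character(other[sel])]
    per_del_tot <- table(factor(ends[sel], levels = del_ids))
    replete <- cl_other %in% c("NEIGHBOUR", "DISTANT")
    per_del_rep <- tapply(replete, factor(ends[sel], levels = del_ids), sum)
    per_del_rep[is.na(per_del_rep)] <- 0
    tot <- mean(per_del_tot)
    rep_mean <- mean(per_del_rep)
  }
  tibble(p_hat = p_hat,
         mean_total_neighbours_of_deleted = tot,
         mean_replete_neighbours_of_deleted = rep_mean,
         fraction_replete_neighbouring =
           if (n_nei + n_dis > 0) n_nei / (n_nei + n_dis) else NA_real_,
         unique_neighbours_per_deleted =
           if (n_del > 0) n_nei / n_del else NA_real_,
         n_deleted = n_del, n_replete = n_nei + n_dis)
}

#' Fraction of replete cells neighbouring a deleted cell
#'
#' `|NEIGHBOUR| / (|NEIGHBOUR| + |DISTANT|)`: the proportion of
#' EGFP-negative cells adjacent to at least one EGFP-positive cell, the
#' per-embryo quantity whose increase with recombination fraction
#' quantifies non-autonomous amplification.
#'
#' @param classes Tibble from [assign_cell_classes()].
#' @return A single fraction.
#' @export
fraction_replete_neighbouring <- function(classes) {
  n_nei <- sum(classes$class == "NEIGHBOUR")
  n_dis <- sum(classes$class == "DISTANT")
  if (n_nei + n_dis == 0) abort("no EGFP-negative cells")
  n_nei / (n_nei + n_dis)
}

#' Unique replete neighbours per deleted cell
#'
#' `|NEIGHBOUR| / |DELETED|`: each replete neighbour counts once no matter
#' how many deleted cells it touches, so neighbour-sharing makes this ratio
#' fall as the deleted fraction rises — the statistic that limits
#' amplification of the non-autonomous effect.
#'
#' @param classes Tibble from [assign_cell_classes()].
#' @return A single ratio.
#' @export
unique_neighbours_per_deleted <- function(classes) {
  n_del <- sum(classes$class == "DELETED")
  if (n_del == 0) abort("no deleted cells")
  sum(classes$class == "NEIGHBOUR") / n_del
}

#' Closed-form neighbour-sharing model on a k-regular mosaic
#'
#' For independent Bernoulli(p) deletion on a graph with degree
#' distribution `q_k`, the probability that a replete cell has at least one
#' deleted neighbour is `f(p) = 1 - sum_k q_k (1 - p)^k` (exact under
#' independence). On a k-regular lattice the expected number of unique
#' replete neighbours per deleted cell is `u(p) = (1 - p) f(p) / p`, with
#' limits `u(0+) = k` and `u(1) = 0`. `u` is strictly decreasing and `f`
#' strictly increasing on (0, 1): amplification is largest at low
#' recombination. The k-regular `u` is an approximation for
#' degree-heterogeneous (Voronoi) mosaics.
#'
#' @param p Deletion probability (vectorised over \[0, 1\]).
#' @param k Degree of the regular lattice (default 6), or
#' @param q_k Optional degree distribution: named numeric vector of
#'   probabilities with names = degrees (overrides `k` for `f`; `u` then
#'   uses the mean degree).
#' @return Tibble: `p`, `f`, `u`.
#' @export
analytic_neighbour_model <- function(p, k = 6, q_k = NULL) {
  stopifnot_scalar_prob(p)
  if (is.null(q_k)) {
    f <- 1 - (1 - p)^k
    kk <- k
  } else {
    if (abs(sum(q_k) - 1) > 1e-8) abort("`q_k` must sum to 1")
    degs <- as.numeric(names(q_k))
    f <- 1 - vapply(p, function(pp) sum(q_k * (1 - pp)^degs), numeric(1))
    kk <- sum(q_k * degs)
  }
  u <- ifelse(p == 0, kk, ifelse(p == 1, 0, (1 - p) * f / p))
  tibble(p = p, f = f, u = u)
}

#' Pearson correlation between two embryo-level columns
#'
#' Thin, pipe-friendly wrapper around [stats::cor.test()] for the
#' embryo-scatter correlations (e.g. eversion against neighbour fraction).
#'
#' @param data A data frame.
#' @param x,y Column names (unquoted or strings).
#' @return Tibble: `r`, `p_value`, `n`, `x`, `y`.
#' @export
pearson_correlate <- function(data, x, y) {
  xq <- rlang::as_name(rlang::ensym(x))
  yq <- rlang::as_name(rlang::ensym(y))
  xv <- data[[xq]]; yv <- data[[yq]]
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]; yv <- yv[keep]
  if (length(xv) < 3) abort("need n >= 3 complete pairs")
  if (sd(xv) == 0 || sd(yv) == 0) abort("constant column: correlation undefined")
  ct <- suppressWarnings(cor.test(xv, yv, method = "pearson"))
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(xv),
         x = xq, y = yq)
}
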