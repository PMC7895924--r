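#' Classify cells as EGFP-positive or EGFP-negative by pixel fraction
#'
#' Applies the two one-sided pixel-fraction rules used to call recombined
#' (lineage-traced) cells from a rescaled EGFP channel: a cell is
#' `EGFP_POS` when at least `frac` of its intracellular pixels have
#' intensity strictly greater than `hi`, `EGFP_NEG` when at least `frac`
#' have intensity strictly less than `lo`, and `UNCLASSIFIED` otherwise
#' (the two rules leave a gap for intermediate intensities; forcing a call
#' there would fabricate data). Intracellular means all pixels of the
#' label, taken after border exclusion, without erosion.
#'
#' @param labels Integer label matrix (0 = background).
#' @param egfp Numeric matrix of the same shape, rescaled to \[0, 1\]
#'   (see [rescale_unit_interval()]).
#' @param hi Upper intensity threshold (default 0.08).
#' @param lo Lower intensity threshold (default 0.06).
#' @param frac Required pixel fraction (default 0.75).
#' @return Tibble: `cell_id`, `call` (factor with levels `EGFP_POS`,
#'   `EGFP_NEG`, `UNCLASSIFIED`), `frac_above_hi`, `frac_below_lo`,
#'   `n_pixels`.
#' @export
classify_egfp <- function(labels, egfp, hi = 0.08, lo = 0.06, frac = 0.75) {
  if (!all(dim(labels) == dim(egfp))) abort("mask and channel shapes differ")
  if (lo > hi) abort("`lo` must not exceed `hi`")
  idx <- labels > 0
  if (!any(idx)) abort("label image has no cells")
  lab <- labels[idx]
  v <- egfp[idx]
  ids <- sort(unique(lab))
  npix <- tabulate(lab)[ids]
  above <- rowsum((v > hi) + 0, lab)[, 1]
  below <- rowsum((v < lo) + 0, lab)[, 1]
  fa <- above / npix
  fb <- below / npix
  call <- ifelse(fa >= frac, "EGFP_POS",
                 ifelse(fb >= frac, "EGFP_NEG", "UNCLASSIFIED"))
  tibble(cell_id = ids,
         call = factor(call, levels = c("EGFP_POS", "EGFP_NEG", "UNCLASSIFIED")),
         frac_above_hi = unname(fa), frac_below_lo = unname(fb),
         n_pixels = npix)
}

#' Build the cell neighbour graph from a label mask
#'
#' Two cells are neighbours when the mask of one overlaps the dilation of
#' the other. Dilation uses a 3 x 3 square structuring element applied
#' `dilation_radius` times (8-connectivity: corner contacts count), the
#' minimal dilation that bridges a one-pixel watershed line between
#' touching cells. Implemented as label-preserving shift comparisons, so
#' no per-cell loop is needed.
#'
#' @param labels Integer label matrix (0 = background), typically after
#'   [exclude_border_cells()] so excluded cells are neither nodes nor
#'   neighbours.
#' @param dilation_radius Dilation radius in pixels (default 1).
#' @param periodic Treat the image as toroidal (synthetic ground-truth
#'   rasters); default `FALSE` for real fields of view.
#' @return Object of class `"neighbour_graph"`: tibble of undirected edges
#'   `a < b`, with attribute `nodes` (all label ids present).
#' @export
build_neighbour_graph <- function(labels, dilation_radius = 1, periodic = FALSE) {
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0) abort("label image has no cells")
  r <- as.integer(dilation_radius)
  pairs_a <- integer(0); pairs_b <- integer(0)
  for (dr in -r:r) {
    for (dc in -r:r) {
      if (dr == 0 && dc == 0) next
      sh <- shift_matrix(labels, dr, dc, periodic = periodic, fill = 0L)
      hit <- labels > 0 & sh > 0 & labels != sh
      if (any(hit)) {
        pairs_a <- c(pairs_a, labels[hit])
        pairs_b <- c(pairs_b, sh[hit])
      }
    }
  }
  edges <- distinct(tibble(a = pmin(pairs_a, pairs_b),
                           b = pmax(pairs_a, pairs_b)))
  edges <- arrange(edges, .data$a, .data$b)
  structure(edges, nodes = ids,
            class = c("neighbour_graph", class(edges)))
}

#' Node degrees of a neighbour graph
#'
#' @param graph A `"neighbour_graph"` from [build_neighbour_graph()] (or a
#'   tibble of edges `a`, `b`); isolated nodes get degree 0 when the graph
#'   carries a `nodes` attribute.
#' @return Tibble: `cell_id`, `degree`.
#' @export
graph_degrees <- function(graph) {
  nodes <- attr(graph, "nodes") %||% sort(unique(c(graph$a, graph$b)))
  deg <- table(factor(c(graph$a, graph$b), levels = nodes))
  tibble(cell_id = as.integer(nodes), degree = as.integer(deg))
}

#' Assign deleted / neighbour / distant cell classes
#'
#' Maps EGFP calls onto the three-class scheme used throughout the
#' analysis: `DELETED` (EGFP_POS, i.e. recombined and gene-deleted),
#' `NEIGHBOUR` (EGFP_NEG with at least one EGFP_POS graph neighbour) and
#' `DISTANT` (EGFP_NEG with none). `UNCLASSIFIED` cells keep that label and
#' are excluded from class counts, but they do not block edges between
#' classified cells.
#'
#' @param graph A `"neighbour_graph"`.
#' @param calls Tibble from [classify_egfp()] covering every graph node.
#' @return Tibble: `cell_id`, `call`, `class` (factor `DELETED`,
#'   `NEIGHBOUR`, `DISTANT`, `UNCLASSIFIED`).
#' @export
assign_cell_classes <- function(graph, calls) {
  nodes <- attr(graph, "nodes") %||% sort(unique(c(graph$a, graph$b)))
  missing <- setdiff(nodes, calls$cell_id)
  if (length(missing)) {
    abort(sprintf("no EGFP call for %d graph node(s), e.g. id %d",
                  length(missing), missing[1]))
  }
  calls <- filter(calls, .data$cell_id %in% nodes)
  pos_ids <- calls$cell_id[calls$call == "EGFP_POS"]
  touched <- unique(c(graph$b[graph$a %in% pos_ids],
                      graph$a[graph$b %in% pos_ids]))
  cls <- ifelse(calls$call == "EGFP_POS", "DELETED",
         ifelse(calls$call == "EGFP_NEG" & calls$cell_id %in% touched, "NEIGHBOUR",
         ifelse(calls$call == "EGFP_NEG", "DISTANT", "UNCLASSIFIED")))
  tibble(cell_id = calls$cell_id, call = calls$call,
         class = factor(cls, levels = c("DELETED", "NEIGHBOUR", "DISTANT",
                                        "UNCLASSIFIED")))
}
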