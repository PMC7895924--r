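#' Rasterize a tessellation into a label image
#'
#' Assigns every pixel the id of its containing cell, producing the 16-bit
#' style label mask that the downstream analysis (and the original imaging
#' pipeline) consumes, together with a ground-truth cell table. Because a
#' Lloyd-relaxed tessellation is the exact Voronoi diagram of its final
#' generators, containment is computed as nearest-generator assignment
#' (toroidal metric on periodic domains), which is exact up to pixel
#' discretisation.
#'
#' @param tess An `"epi_tessellation"` from [generate_tessellation()].
#' @param pixel_size Domain units per pixel (default 1: one pixel per unit).
#' @return A list with `labels` (integer matrix; rows = image rows (RC axis),
#'   columns = image columns (ML axis); label 0 never occurs on a full
#'   tessellation) and `truth` (tibble: `cell_id`, `x`, `y`,
#'   `true_area_px2` from the polygon shoelace area, `true_degree`,
#'   `n_pixels` rasterized pixel count). Cells too thin to receive any pixel
#'   are dropped from both with a warning and remaining labels are renumbered
#'   consecutively (original ids kept in `orig_id`).
#' @export
rasterize_labels <- function(tess, pixel_size = 1) {
  stopifnot(inherits(tess, "epi_tessellation"))
  W <- tess$domain[1]; H <- tess$domain[2]
  ncol_px <- round(W / pixel_size)
  nrow_px <- round(H / pixel_size)
  px <- (rep(seq_len(ncol_px), each = nrow_px) - 0.5) * pixel_size
  py <- (rep(seq_len(nrow_px), times = ncol_px) - 0.5) * pixel_size

  seeds <- tess$seeds
  ids <- seq_len(nrow(seeds))
  if (tess$periodic) {
    margin <- 3 * sqrt(W * H / nrow(seeds))
    off <- expand.grid(dx = c(0, -W, W), dy = c(0, -H, H))
    xs <- as.vector(outer(seeds[, 1], off$dx, `+`))
    ys <- as.vector(outer(seeds[, 2], off$dy, `+`))
    rep_ids <- rep(ids, times = nrow(off))
    keep <- xs > -margin & xs < W + margin & ys > -margin & ys < H + margin
    seeds <- cbind(xs[keep], ys[keep])
    ids <- rep_ids[keep]
  }
  lab <- as.integer(as.character(
    class::knn1(seeds, cbind(px, py), factor(ids))))
  labels <- matrix(lab, nrow = nrow_px, ncol = ncol_px)

  n <- nrow(tess$cells)
  counts <- tabulate(labels, nbins = n)
  truth <- mutate(tess$cells,
                  true_area_px2 = .data$area / pixel_size^2,
                  true_degree = .data$degree,
                  n_pixels = counts,
                  orig_id = .data$cell_id)
  if (any(counts == 0)) {
    gone <- which(counts == 0)
    warn(sprintf("%d cell(s) thinner than one pixel vanished during rasterization and were removed", length(gone)))
    truth <- filter(truth, .data$n_pixels > 0)
    remap <- integer(n)
    remap[truth$orig_id] <- seq_len(nrow(truth))
    labels[] <- remap[labels]
    truth$cell_id <- seq_len(nrow(truth))
  }
  list(labels = labels,
       truth = select(truth, "cell_id", "orig_id", "x", "y",
                      "true_area_px2", "true_degree", "n_pixels"))
}

#' Assign a Bernoulli mosaic of recombined cells
#'
#' Emulates tamoxifen-induced Cre recombination of a membrane reporter:
#' each cell independently switches (tdTomato to EGFP) with probability `p`,
#' the recombination fraction. Deterministic given `seed`.
#'
#' @param tess An `"epi_tessellation"`, or an integer number of cells.
#' @param p Recombination probability in \[0, 1\].
#' @param seed Integer seed.
#' @return A tibble with `cell_id` and logical `recombined`.
#' @export
assign_mosaic <- function(tess, p, seed = 1L) {
  stopifnot_scalar_prob(p)
  n <- if (inherits(tess, "epi_tessellation")) nrow(tess$cells) else as.integer(tess)
  flags <- with_seed(seed, runif(n) < p)
  tibble(cell_id = seq_len(n), recombined = flags)
}
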