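#' Exclude cells touching the image border
#'
#' Replaces all labels within a `border_width`-pixel strip around the image
#' with background (0), and removes every cell that lost at least one pixel
#' from downstream per-cell statistics. Truncated cells are excluded
#' entirely rather than analysed as partial masks, since clipped shapes
#' would bias area and perimeter.
#'
#' @param labels Integer label matrix (0 = background).
#' @param border_width Strip width in pixels (default 30). Must be
#'   non-negative and less than half the smaller image dimension.
#' @return A list with `labels` (the masked image) and `excluded`
#'   (integer vector of removed cell ids). Idempotent at fixed width.
#' @export
exclude_border_cells <- function(labels, border_width = 30) {
  nr <- nrow(labels); nc <- ncol(labels)
  if (border_width < 0 || 2 * border_width >= min(nr, nc)) {
    abort("`border_width` must be >= 0 and < half the smaller image dimension")
  }
  if (border_width == 0) {
    return(list(labels = labels, excluded = integer(0)))
  }
  b <- border_width
  strip <- matrix(FALSE, nr, nc)
  strip[c(seq_len(b), (nr - b + 1L):nr), ] <- TRUE
  strip[, c(seq_len(b), (nc - b + 1L):nc)] <- TRUE
  excluded <- sort(unique(labels[strip & labels > 0]))
  out <- labels
  out[out %in% excluded] <- 0L
  list(labels = out, excluded = excluded)
}

#' Rescale an intensity channel to the unit interval
#'
#' Linear min-max rescale to \[0, 1\], the normalisation applied to
#' fluorescence channels before pixel-fraction thresholding. Affine, so the
#' rank order of pixel values is preserved.
#'
#' @param channel Numeric matrix.
#' @return Matrix with minimum 0 and maximum 1.
#' @export
rescale_unit_interval <- function(channel) {
  rng <- range(channel, na.rm = TRUE)
  if (!is.finite(diff(rng)) || diff(rng) == 0) {
    abort("channel is constant: rescaling (and thresholding) undefined")
  }
  (channel - rng[1]) / diff(rng)
}

#' Per-cell shape and orientation features
#'
#' Computes, for every label, the features used to characterise apical cell
#' shape: area `A` (pixel count), perimeter `P` (oriented-contour length:
#' sum of unit and sqrt(2) steps along the traced 8-connected boundary,
#' via [EBImage::ocontour()]), solidity (`A` divided by the pixel count of
#' the filled convex hull, enumerated boundary-inclusively over pixel
#' centres), and major/minor axis lengths with orientation from the second
#' central moments of the pixel set (equivalent-ellipse convention:
#' axis length = 4 sqrt(eigenvalue of the coordinate covariance)).
#'
#' Axis convention: image rows run along the rostrocaudal (RC) axis and
#' columns along the mediolateral (ML) axis. `orientation_deg` is the acute
#' angle between the cell's long axis and the RC axis, folded to
#' \[0, 90\] degrees, so 90 means a mediolaterally elongated cell.
#' Orientation is `NA` for cells with (numerically) equal axes. Single-pixel
#' cells have degenerate axes and are flagged.
#'
#' @param labels Integer label matrix (0 = background).
#' @param pixel_size_um Physical pixel size; `area_um2` is included when
#'   given.
#' @return Tibble: `cell_id`, `area`, `perimeter`, `solidity`,
#'   `major_axis`, `minor_axis`, `orientation_deg`, `degenerate`.
#' @export
compute_cell_features <- function(labels, pixel_size_um = NULL) {
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0) abort("label image has no nonzero labels")
  idx <- which(labels > 0)
  lab <- labels[idx]
  rr <- ((idx - 1L) %% nrow(labels)) + 1L
  cc <- ((idx - 1L) %/% nrow(labels)) + 1L
  rows_by <- split(rr, lab)
  cols_by <- split(cc, lab)
  per <- perimeter_by_label(labels, ids)

  recs <- purrr::map(as.character(ids), function(key) {
    r <- rows_by[[key]]; c <- cols_by[[key]]
    a <- length(r)
    if (a == 1) {
      return(tibble(area = 1, solidity = 1, major_axis = 0, minor_axis = 0,
                    orientation_deg = NA_real_, degenerate = TRUE))
    }
    mu <- cbind(r - mean(r), c - mean(c))
    cov <- crossprod(mu) / a
    eg <- eigen(cov, symmetric = TRUE)
    major <- 4 * sqrt(max(eg$values[1], 0))
    minor <- 4 * sqrt(max(eg$values[2], 0))
    ori <- if (eg$values[1] - eg$values[2] < 1e-9 * (eg$values[1] + 1e-12)) {
      NA_real_
    } else {
      v <- eg$vectors[, 1]               # v[1]: RC (row) comp, v[2]: ML (col)
      ang <- abs(atan2(v[2], v[1])) * 180 / pi
      if (ang > 90) ang <- 180 - ang
      ang
    }
    tibble(area = a, solidity = a / convex_pixel_count(r, c),
           major_axis = major, minor_axis = minor,
           orientation_deg = ori, degenerate = FALSE)
  })
  out <- mutate(bind_rows(recs), cell_id = ids, perimeter = per,
                .before = 1)
  out <- select(out, "cell_id", "area", "perimeter", "solidity",
                "major_axis", "minor_axis", "orientation_deg", "degenerate")
  if (!is.null(pixel_size_um)) {
    out <- mutate(out, area_um2 = .data$area * pixel_size_um^2)
  }
  out
}

# Oriented-contour perimeter per label: step lengths (1 or sqrt(2)) along
# the closed traced boundary.
perimeter_by_label <- function(labels, ids) {
  oc <- EBImage::ocontour(labels)
  unname(vapply(as.character(ids), function(key) {
    xy <- oc[[key]]
    if (is.null(xy) || nrow(xy) < 2) return(0)
    d <- sqrt(rowSums((xy - xy[c(2:nrow(xy), 1), ])^2))
    sum(d)
  }, numeric(1)))
}

# Pixel count of the filled convex hull of a pixel set (centres on the hull
# boundary count as inside).
convex_pixel_count <- function(r, c) {
  pts <- cbind(r, c)
  h <- grDevices::chull(pts)
  hull <- pts[h, , drop = FALSE]
  if (nrow(hull) <= 2) return(length(r))
  gr <- seq(min(r), max(r)); gc <- seq(min(c), max(c))
  pr <- rep(gr, times = length(gc)); pc <- rep(gc, each = length(gr))
  # points_in_convex expects clockwise order (signed area < 0)
  if (polygon_area_signed(hull) > 0) hull <- hull[rev(seq_len(nrow(hull))), ]
  sum(points_in_convex(pr, pc, hull))
}

polygon_area_signed <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  i2 <- c(seq_len(nrow(xy))[-1], 1L)
  sum(x * y[i2] - x[i2] * y) / 2
}

#' Histogram of apical long-axis orientations
#'
#' Bins orientations over \[0, 90\] degrees and reports the median
#' orientation (midpoint convention for even counts). Mediolaterally
#' polarised epithelia give medians above 45 degrees.
#'
#' @param features Feature tibble from [compute_cell_features()] (or any
#'   tibble with `orientation_deg`); `NA` orientations are dropped.
#' @param bin_width_deg Bin width (default 10; must divide 90).
#' @param group Optional group label carried into the result.
#' @return Object of class `"orientation_histogram"`: tibble with
#'   `bin_lo`, `bin_hi`, `count` plus attributes `median_deg`, `n`, `group`.
#' @export
orientation_histogram <- function(features, bin_width_deg = 10, group = NULL) {
  ori <- features$orientation_deg
  ori <- ori[!is.na(ori)]
  if (length(ori) == 0) abort("no oriented cells")
  if (90 %% bin_width_deg != 0) abort("`bin_width_deg` must divide 90")
  edges <- seq(0, 90, by = bin_width_deg)
  bin <- pmin(findInterval(ori, edges, rightmost.closed = TRUE),
              length(edges) - 1L)
  out <- tibble(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                count = tabulate(bin, nbins = length(edges) - 1L))
  structure(out, median_deg = median(ori), n = length(ori),
            group = group %||% NA_character_,
            class = c("orientation_histogram", class(out)))
}

#' Chi-square homogeneity test between two orientation histograms
#'
#' Compares two binned orientation distributions with a chi-square test of
#' homogeneity. Yates continuity correction is applied only when the
#' contingency table is 2 x 2 (the correction is defined for one degree of
#' freedom).
#'
#' @param hist_a,hist_b `"orientation_histogram"` objects (or tibbles with
#'   `bin_lo`, `bin_hi`, `count`) on identical bin edges.
#' @param yates Apply Yates continuity correction when the table is 2 x 2.
#' @return Tibble with `statistic`, `df`, `p_value`, `yates_applied`.
#' @export
chi2_homogeneity <- function(hist_a, hist_b, yates = TRUE) {
  if (!isTRUE(all.equal(hist_a$bin_lo, hist_b$bin_lo)) ||
      !isTRUE(all.equal(hist_a$bin_hi, hist_b$bin_hi))) {
    abort("histograms must share bin edges")
  }
  keep <- hist_a$count + hist_b$count > 0
  tab <- rbind(hist_a$count[keep], hist_b$count[keep])
  if (ncol(tab) < 2) abort("fewer than two occupied bins; merge bins")
  exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp_counts == 0)) abort("zero expected count; merge bins")
  use_yates <- yates && all(dim(tab) == c(2L, 2L))
  ht <- suppressWarnings(chisq.test(tab, correct = use_yates))
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, yates_applied = use_yates)
}
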