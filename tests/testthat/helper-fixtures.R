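# Shared fixtures, built lazily and cached for the session: a small periodic
# hexagonal lattice (exact degree-6 truth) with its raster, and helpers to
# fabricate calls/classes without rendering.

.fixture_cache <- new.env(parent = emptyenv())

hex_fixture <- function(n = 144, px = c(128, 128), seed = 4) {
  key <- paste0("hex_", n, "_", px[1], "_", seed)
  if (is.null(.fixture_cache[[key]])) {
    tess <- generate_tessellation(tessellation_spec(
      n, px, periodic = TRUE, lattice_mode = "hexagonal", seed = seed))
    ras <- rasterize_labels(tess)
    graph <- build_neighbour_graph(ras$labels, 1, periodic = TRUE)
    .fixture_cache[[key]] <- list(tess = tess, ras = ras, graph = graph)
  }
  .fixture_cache[[key]]
}

truth_graph <- function(tess) {
  structure(tess$edges, nodes = tess$cells$cell_id,
            class = c("neighbour_graph", class(tess$edges)))
}

calls_from_flags <- function(flags, ids = seq_along(flags)) {
  tibble::tibble(
    cell_id = ids,
    call = factor(ifelse(flags, "EGFP_POS", "EGFP_NEG"),
                  levels = c("EGFP_POS", "EGFP_NEG", "UNCLASSIFIED")))
}

# deleted cells given by id on a lattice; classes via the package mapper
classes_on_lattice <- function(graph, n, deleted_ids) {
  flags <- seq_len(n) %in% deleted_ids
  assign_cell_classes(graph, calls_from_flags(flags))
}

# independent convex-hull pixel-count oracle (brute force over candidate
# pixels; half-plane test written separately from the package's)
hull_pixel_count_oracle <- function(r, c) {
  pts <- unique(cbind(r, c))
  h <- grDevices::chull(pts)
  hull <- pts[h, , drop = FALSE]
  gr <- expand.grid(r = min(r):max(r), c = min(c):max(c))
  inside <- vapply(seq_len(nrow(gr)), function(i) {
    p <- c(gr$r[i], gr$c[i])
    signs <- vapply(seq_len(nrow(hull)), function(k) {
      k2 <- if (k == nrow(hull)) 1L else k + 1L
      (hull[k2, 1] - hull[k, 1]) * (p[2] - hull[k, 2]) -
        (hull[k2, 2] - hull[k, 2]) * (p[1] - hull[k, 1])
    }, numeric(1))
    all(signs <= 1e-9) || all(signs >= -1e-9)
  }, logical(1))
  sum(inside)
}

# full hypergeometric enumeration oracle for the two-sided Fisher p
fisher_enumeration_oracle <- function(tab) {
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  xs <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(xs, m, n2, k)
  obs <- stats::dhyper(tab[1, 1], m, n2, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
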