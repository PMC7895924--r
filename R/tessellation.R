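#' Specify a synthetic apical tessellation
#'
#' Constructs the parameter object consumed by [generate_tessellation()].
#' The tessellation stands in for the apical surface of a pseudostratified
#' neuroepithelium: a space-filling mosaic of convex cells in which the
#' average cell has six neighbours (Lewis' law). Two lattice modes are
#' provided: `"voronoi"` (Lloyd-relaxed random generators, realistic degree
#' heterogeneity) and `"hexagonal"` (exact degree-6 honeycomb, used for
#' closed-form validation).
#'
#' @param n_cells Number of cells (>= 3). In hexagonal mode this must factor
#'   into `nx * ny` grid dimensions that tile the domain (`ny` even when
#'   `periodic`).
#' @param domain_size Width and height of the domain in pixels (each >= 32).
#' @param periodic Logical; if `TRUE` the domain is toroidal (no boundary),
#'   which is the mode used for statistical validation since closed-form
#'   neighbour statistics assume no edge effects.
#' @param lloyd_iterations Non-negative integer; Lloyd (centroidal Voronoi)
#'   relaxation steps applied before polygon extraction. Ignored in
#'   hexagonal mode, which is already centroidal.
#' @param lattice_mode `"voronoi"` or `"hexagonal"`.
#' @param seed Integer RNG seed; all generator placement flows from it.
#' @return A list of class `"tessellation_spec"`.
#' @export
#' @examples
#' spec <- tessellation_spec(100, c(128, 128), seed = 1)
#' tess <- generate_tessellation(spec)
#' mean(tess$cells$degree)
tessellation_spec <- function(n_cells,
                              domain_size = c(512, 512),
                              periodic = TRUE,
                              lloyd_iterations = 2,
                              lattice_mode = c("voronoi", "hexagonal"),
                              seed = 1L) {
  lattice_mode <- match.arg(lattice_mode)
  if (n_cells < 3) abort("`n_cells` must be >= 3")
  if (length(domain_size) != 2 || any(domain_size < 32)) {
    abort("`domain_size` must be two values, each >= 32 px")
  }
  if (lloyd_iterations < 0) abort("`lloyd_iterations` must be >= 0")
  structure(
    list(n_cells = as.integer(n_cells),
         domain_size = as.numeric(domain_size),
         periodic = isTRUE(periodic),
         lloyd_iterations = as.integer(lloyd_iterations),
         lattice_mode = lattice_mode,
         seed = as.integer(seed)),
    class = "tessellation_spec")
}

#' Generate a synthetic apical tessellation
#'
#' Produces cell polygons, generator points, the true adjacency graph and
#' per-cell true areas/degrees. On a periodic (toroidal) domain every
#' trivalent tessellation has mean degree exactly 6 (Euler's formula);
#' non-periodic domains have boundary cells of lower degree, emulating a
#' microscope field of view.
#'
#' @param spec A [tessellation_spec()].
#' @return An object of class `"epi_tessellation"`: a list with
#'   `cells` (tibble: `cell_id`, `x`, `y`, `area`, `degree`),
#'   `polygons` (list of 2-column vertex matrices, domain coordinates),
#'   `edges` (tibble `a`, `b`, the true adjacency, `a < b`),
#'   `seeds` (generator matrix; the tessellation is the exact Voronoi
#'   diagram of these points), `domain`, `periodic`, `lattice_mode`.
#' @export
generate_tessellation <- function(spec) {
  stopifnot(inherits(spec, "tessellation_spec"))
  if (spec$lattice_mode == "hexagonal") {
    return(hex_tessellation(spec))
  }
  W <- spec$domain_size[1]; H <- spec$domain_size[2]
  n <- spec$n_cells
  seeds <- with_seed(spec$seed, cbind(runif(n, 0, W), runif(n, 0, H)))
  for (i in seq_len(spec$lloyd_iterations)) {
    vt <- voronoi_tiles(seeds, c(W, H), spec$periodic)
    cent <- t(vapply(vt$polygons, polygon_centroid, numeric(2)))
    if (spec$periodic) {
      cent[, 1] <- cent[, 1] %% W
      cent[, 2] <- cent[, 2] %% H
    } else {
      cent[, 1] <- pmin(pmax(cent[, 1], 1e-6), W - 1e-6)
      cent[, 2] <- pmin(pmax(cent[, 2], 1e-6), H - 1e-6)
    }
    seeds <- cent
  }
  vt <- voronoi_tiles(seeds, c(W, H), spec$periodic)
  new_tessellation(spec, seeds, vt$polygons, vt$edges)
}

# Voronoi tiles + tile adjacency via deldir. Periodic domains are handled by
# 3x3 replication of the generators; tiles/edges of the central copy are
# extracted and replicated indices folded back mod n.
voronoi_tiles <- function(seeds, domain, periodic) {
  W <- domain[1]; H <- domain[2]
  n <- nrow(seeds)
  if (periodic) {
    off <- expand.grid(dx = c(0, -1, 1), dy = c(0, -1, 1))
    xs <- as.vector(outer(seeds[, 1], off$dx * W, `+`))
    ys <- as.vector(outer(seeds[, 2], off$dy * H, `+`))
    dd <- deldir::deldir(xs, ys, rw = c(-W, 2 * W, -H, 2 * H),
                         suppressMsge = TRUE)
    tl <- deldir::tile.list(dd)
    polys <- lapply(tl[seq_len(n)], function(t) cbind(t$x, t$y))
    ds <- dd$dirsgs
    keep <- ds$ind1 <= n | ds$ind2 <= n
    a <- ((ds$ind1[keep] - 1L) %% n) + 1L
    b <- ((ds$ind2[keep] - 1L) %% n) + 1L
    if (any(a == b)) {
      warn("tessellation too small for periodic domain: cell adjacent to its own image; self-edges dropped")
      drop <- a == b
      a <- a[!drop]; b <- b[!drop]
    }
  } else {
    dd <- deldir::deldir(seeds[, 1], seeds[, 2], rw = c(0, W, 0, H),
                         suppressMsge = TRUE)
    tl <- deldir::tile.list(dd)
    polys <- lapply(tl, function(t) cbind(t$x, t$y))
    a <- dd$dirsgs$ind1
    b <- dd$dirsgs$ind2
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  edges <- distinct(tibble(a = lo, b = hi))
  list(polygons = polys, edges = edges)
}

# Analytic honeycomb: one prototype hexagon (the Euclidean Voronoi cell of a
# site in an offset-row lattice) translated to every centre.
hex_tessellation <- function(spec) {
  W <- spec$domain_size[1]; H <- spec$domain_size[2]
  n <- spec$n_cells
  dims <- hex_grid_dims(n, W, H, spec$periodic)
  nx <- dims[1]; ny <- dims[2]
  dx <- W / nx; dy <- H / ny

  ij <- expand.grid(j = 0:(nx - 1), i = 0:(ny - 1))
  cx <- ((ij$j + 0.5 * (ij$i %% 2) + 0.25) * dx) %% W
  cy <- (ij$i + 0.5) * dy
  seeds <- cbind(cx, cy)

  # neighbour offsets from a site: E/W and the four offset-row diagonals
  offs <- rbind(c(dx, 0), c(-dx, 0),
                c(dx / 2, dy), c(-dx / 2, dy),
                c(dx / 2, -dy), c(-dx / 2, -dy))
  proto <- cbind(c(-dx, dx, dx, -dx), c(-dy, -dy, dy, dy))
  for (k in seq_len(nrow(offs))) {
    proto <- clip_halfplane(proto, offs[k, ] / 2, offs[k, ])
  }

  id_of <- function(i, j) i * nx + j + 1L
  i <- ij$i; j <- ij$j
  nb <- list()
  add_nb <- function(ii, jj) {
    if (spec$periodic) {
      ok <- rep(TRUE, length(ii))
      ii <- ii %% ny; jj <- jj %% nx
    } else {
      ok <- ii >= 0 & ii < ny & jj >= 0 & jj < nx
    }
    tibble(a = id_of(i, j)[ok], b = id_of(ii[ok], jj[ok]))
  }
  odd <- i %% 2
  edges <- bind_rows(
    add_nb(i, j + 1L),                # E
    add_nb(i + 1L, j + odd),          # NE (parity-dependent column)
    add_nb(i + 1L, j - 1L + odd)      # NW
  )
  edges <- distinct(tibble(a = pmin(edges$a, edges$b),
                           b = pmax(edges$a, edges$b)))

  polys <- lapply(seq_len(n), function(k) {
    cbind(proto[, 1] + seeds[k, 1], proto[, 2] + seeds[k, 2])
  })
  new_tessellation(spec, seeds, polys, edges)
}

# Pick the hexagonal grid factorisation of n closest to isotropic hexagons
# (dy/dx = sqrt(3)/2) for the given domain aspect.
hex_grid_dims <- function(n, W, H, periodic) {
  divs <- which(n %% seq_len(n) == 0)
  cand <- tibble(nx = divs, ny = n %/% divs)
  if (periodic) cand <- filter(cand, .data$ny %% 2 == 0)
  cand <- filter(cand, .data$nx >= 2, .data$ny >= 2)
  if (nrow(cand) == 0) {
    abort(paste0("hexagonal mode: n_cells = ", n,
                 " cannot tile the domain (need nx * ny with ny even >= 2)"))
  }
  # anisotropy of the resulting hexagons relative to regular ones
  aniso <- abs(log(((H / cand$ny) / (W / cand$nx)) / (sqrt(3) / 2)))
  c(cand$nx[which.min(aniso)], cand$ny[which.min(aniso)])
}

new_tessellation <- function(spec, seeds, polys, edges) {
  n <- spec$n_cells
  deg <- tabulate(c(edges$a, edges$b), nbins = n)
  areas <- vapply(polys, polygon_area, numeric(1))
  structure(
    list(cells = tibble(cell_id = seq_len(n),
                        x = seeds[, 1], y = seeds[, 2],
                        area = areas, degree = deg),
         polygons = polys,
         edges = edges,
         seeds = seeds,
         domain = spec$domain_size,
         periodic = spec$periodic,
         lattice_mode = spec$lattice_mode,
         spec = spec),
    class = "epi_tessellation")
}

#' @export
print.epi_tessellation <- function(x, ...) {
  cat(sprintf("<epi_tessellation> %d cells, %s, %s domain %g x %g px, mean degree %.3f\n",
              nrow(x$cells), x$lattice_mode,
              if (x$periodic) "periodic" else "bounded",
              x$domain[1], x$domain[2], mean(x$cells$degree)))
  invisible(x)
}

#' @rdname tidy.lewis_fit
#' @export
tidy.epi_tessellation <- function(x, ...) x$cells
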