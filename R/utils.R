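#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select group_by summarise ungroup arrange
#'   left_join inner_join bind_rows distinct n count rename pull across
#' @importFrom stats rnorm runif rbinom sd lm coef cor.test t.test chisq.test
#'   fisher.test power.t.test median quantile setNames
#' @importFrom utils head tail
NULL

# Deterministic child seed: every stochastic operation draws its own stream
# from one user-facing integer seed, so cohort members are reproducible
# independently of evaluation order. Kept strictly below 2^31 - 1.
child_seed <- function(seed, k) {
  (abs(as.integer(seed)) %% 1000000L) * 2048L + (as.integer(k) %% 2048L)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Shoelace signed area of a polygon given as a 2-column matrix (x, y).
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  i2 <- c(seq_len(nrow(xy))[-1], 1L)
  abs(sum(x * y[i2] - x[i2] * y)) / 2
}

polygon_centroid <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  i2 <- c(seq_len(nrow(xy))[-1], 1L)
  cr <- x * y[i2] - x[i2] * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(xy))
  c(sum((x + x[i2]) * cr), sum((y + y[i2]) * cr)) / (6 * a)
}

# Clip a convex polygon by the half plane {q : (q - m) . nrm <= 0}
# (Sutherland-Hodgman, one plane).
clip_halfplane <- function(xy, m, nrm) {
  d <- (xy[, 1] - m[1]) * nrm[1] + (xy[, 2] - m[2]) * nrm[2]
  n <- nrow(xy)
  if (all(d <= 0)) return(xy)
  if (all(d > 0)) return(xy[0, , drop = FALSE])
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    di <- d[i]; dj <- d[j]
    if (di <= 0) out <- rbind(out, xy[i, ])
    if ((di <= 0) != (dj <= 0)) {
      t <- di / (di - dj)
      out <- rbind(out, xy[i, ] + t * (xy[j, ] - xy[i, ]))
    }
  }
  out
}

# Points-in-convex-polygon test, boundary-inclusive to within eps.
# Polygon must be in clockwise order (signed area < 0).
# Used for convex-image pixel enumeration (solidity).
points_in_convex <- function(px, py, xy, eps = 1e-7) {
  n <- nrow(xy)
  tol <- eps * max(diff(range(xy[, 1])), diff(range(xy[, 2])), 1)
  inside <- rep(TRUE, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cross <- (xy[j, 1] - xy[i, 1]) * (py - xy[i, 2]) -
      (xy[j, 2] - xy[i, 2]) * (px - xy[i, 1])
    inside <- inside & (cross <= tol)
  }
  inside
}

# Shift an integer/numeric matrix by (dr, dc); vacated cells get `fill`,
# or wrap toroidally when periodic.
shift_matrix <- function(m, dr, dc, periodic = FALSE, fill = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  if (periodic) {
    ri <- ((seq_len(nr) - 1L - dr) %% nr) + 1L
    ci <- ((seq_len(nc) - 1L - dc) %% nc) + 1L
    return(m[ri, ci, drop = FALSE])
  }
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(rs) && length(cs)) {
    out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  }
  out
}

stopifnot_scalar_prob <- function(p, what = "p") {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort(sprintf("`%s` must lie in [0, 1]", what))
  }
  invisible(p)
}
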