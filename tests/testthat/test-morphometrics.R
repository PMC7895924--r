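test_that("border exclusion removes truncated cells and is idempotent", {
  img <- matrix(0L, 200, 200)
  img[60:100, 60:100] <- 1L            # wholly inside [31..170]^2
  img[10:20, 80:120] <- 2L             # wholly inside the 30 px strip
  img[25:40, 140:160] <- 3L            # straddles the strip
  out <- exclude_border_cells(img, 30)
  expect_identical(out$excluded, c(2L, 3L))
  expect_true(all(out$labels %in% c(0L, 1L)))
  expect_identical(sum(out$labels == 1L), sum(img == 1L))
  again <- exclude_border_cells(out$labels, 30)
  expect_identical(again$labels, out$labels)
  expect_identical(again$excluded, integer(0))
  # width 0 is the identity
  id <- exclude_border_cells(img, 0)
  expect_identical(id$labels, img)
  expect_identical(id$excluded, integer(0))
  expect_error(exclude_border_cells(img, 100), "border_width")
})

test_that("unit-interval rescale is a rank-preserving affine map", {
  m <- matrix(c(10, 20, 30, 20), 2)
  r <- rescale_unit_interval(m)
  expect_equal(sort(unique(as.vector(r))), c(0, 0.5, 1))
  full <- matrix(seq(0, 1, length.out = 9), 3)
  expect_equal(rescale_unit_interval(full), full)
  expect_error(rescale_unit_interval(matrix(5, 3, 3)), "constant")
  set.seed(1)
  x <- matrix(rnorm(100), 10)
  expect_identical(order(rescale_unit_interval(x)), order(x))
})

test_that("cell features match hand-computable shapes", {
  img <- matrix(0L, 40, 60)
  img[5:14, 5:14] <- 1L                # 10 x 10 square
  img[20:29, 10:39] <- 2L              # 10 rows x 30 cols: elongated along ML
  f <- compute_cell_features(img)
  sq <- f[f$cell_id == 1, ]
  expect_equal(sq$area, 100)
  expect_equal(sq$solidity, 1)
  expect_equal(sq$perimeter, 36)       # oriented-contour convention
  expect_true(is.na(sq$orientation_deg))  # isotropic: no long axis
  rect <- f[f$cell_id == 2, ]
  expect_equal(rect$orientation_deg, 90)  # long side along columns = ML
  expect_gt(rect$major_axis, rect$minor_axis)
})

test_that("solidity equals pixel count over enumerated convex-hull pixels", {
  # notch in the middle of an edge: hull is the full square, 375/400 exactly
  n2 <- matrix(0L, 30, 30)
  n2[5:24, 5:24] <- 1L
  n2[5:9, 12:16] <- 0L
  expect_equal(compute_cell_features(n2)$solidity, 375 / 400)
  # corner notch: hull cuts the corner; compare to an independent oracle
  n1 <- matrix(0L, 30, 30)
  n1[5:24, 5:24] <- 1L
  n1[5:9, 20:24] <- 0L
  idx <- which(n1 == 1L)
  r <- ((idx - 1L) %% 30L) + 1L
  c <- ((idx - 1L) %/% 30L) + 1L
  expect_equal(compute_cell_features(n1)$solidity,
               375 / hull_pixel_count_oracle(r, c))
})

test_that("orientation matches an analytically constructed ellipse within 2 degrees", {
  for (ang in c(20, 45, 70)) {
    th <- ang * pi / 180
    gr <- expand.grid(r = -60:60, c = -60:60)
    # major axis a = 40, minor b = 15, rotated by `ang` from the row axis
    u <- gr$r * cos(th) + gr$c * sin(th)
    v <- -gr$r * sin(th) + gr$c * cos(th)
    inside <- (u / 40)^2 + (v / 15)^2 <= 1
    img <- matrix(0L, 121, 121)
    img[cbind(gr$r[inside] + 61, gr$c[inside] + 61)] <- 1L
    f <- compute_cell_features(img)
    expect_lt(abs(f$orientation_deg - ang), 2)
  }
})

test_that("rotating the image by 90 degrees maps orientation to its complement", {
  set.seed(8)
  gr <- expand.grid(r = -40:40, c = -40:40)
  th <- 33 * pi / 180
  u <- gr$r * cos(th) + gr$c * sin(th)
  v <- -gr$r * sin(th) + gr$c * cos(th)
  inside <- (u / 30)^2 + (v / 12)^2 <= 1
  img <- matrix(0L, 81, 81)
  img[cbind(gr$r[inside] + 41, gr$c[inside] + 41)] <- 1L
  rot <- t(img)[, nrow(img):1]         # 90 degree rotation
  o1 <- compute_cell_features(img)$orientation_deg
  o2 <- compute_cell_features(rot)$orientation_deg
  expect_equal(o2, 90 - o1, tolerance = 1e-6)
})

test_that("orientation histogram bins [0, 90] and reports the median", {
  h <- orientation_histogram(tibble::tibble(orientation_deg = rep(90, 7)))
  expect_equal(sum(h$count), 7)
  expect_equal(h$count[h$bin_lo == 80], 7)
  expect_equal(attr(h, "median_deg"), 90)
  h2 <- orientation_histogram(tibble::tibble(orientation_deg = c(30, 60)))
  expect_equal(attr(h2, "median_deg"), 45)   # midpoint convention
  set.seed(13)
  h3 <- orientation_histogram(tibble::tibble(orientation_deg = runif(5000, 0, 90)))
  expect_equal(attr(h3, "median_deg"), 45, tolerance = 2 / 45)
  expect_equal(sum(h3$count), 5000)
})

test_that("chi-square homogeneity applies Yates only to 2x2 tables", {
  mkhist <- function(counts, w = 45) {
    tibble::tibble(bin_lo = seq(0, 90 - w, w), bin_hi = seq(w, 90, w),
                   count = counts)
  }
  same <- chi2_homogeneity(mkhist(c(10, 20)), mkhist(c(10, 20)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # hand-computed Yates: E = 15 everywhere, X2 = 4 * (5 - 0.5)^2 / 15 = 5.4
  y <- chi2_homogeneity(mkhist(c(10, 20)), mkhist(c(20, 10)), yates = TRUE)
  expect_true(y$yates_applied)
  expect_equal(y$statistic, 5.4)
  expect_equal(y$p_value, 0.0201, tolerance = 1e-2)
  # disjoint single-bin occupancy, n = 50 each
  d <- chi2_homogeneity(mkhist(c(50, 0)), mkhist(c(0, 50)))
  expect_lt(d$p_value, 1e-9)
  # > 2 bins: correction not applied even when requested
  h10a <- orientation_histogram(tibble::tibble(orientation_deg = runif(200, 0, 90)))
  h10b <- orientation_histogram(tibble::tibble(orientation_deg = runif(200, 0, 90)))
  res <- chi2_homogeneity(h10a, h10b, yates = TRUE)
  expect_false(res$yates_applied)
  expect_error(chi2_homogeneity(mkhist(c(10, 20)), mkhist(c(5, 40, 1),
                                                          w = 30)),
               "bin")
})
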