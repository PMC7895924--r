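mk_trace <- function(areas, t = seq_along(areas) - 1, cell = 1L, embryo = 1L,
                     group = "control") {
  tibble::tibble(cell_id = cell, embryo_id = embryo, group = group,
                 t_min = t, area_px2 = areas)
}

test_that("alignment places T = 0 at the (first) maximum and normalises to 100", {
  a <- align_at_max(mk_trace(c(1, 2, 3)))
  expect_equal(a$aligned_t, c(-2, -1, 0))
  expect_equal(a$norm_area, c(100 / 3, 200 / 3, 100))
  # constant trace: tie broken by the earliest timepoint
  b <- align_at_max(mk_trace(c(5, 5, 5)))
  expect_equal(b$aligned_t, c(0, 1, 2))
  expect_true(all(b$norm_area == 100))
  c3 <- align_at_max(mk_trace(c(2, 5, 3, 4)))
  expect_equal(c3$aligned_t, c(-1, 0, 1, 2))
  expect_error(align_at_max(mk_trace(c(1, -2, 3))), "positive")
})

test_that("alignment preserves the raw-area multiset and flags short sides", {
  set.seed(5)
  tr <- simulate_area_traces(make_trace_cohort(2, 4), dynamics_spec(seed = 3))
  al <- align_at_max(tr)
  expect_equal(sort(al$area_px2), sort(tr$area_px2))
  by_cell <- dplyr::summarise(dplyr::group_by(al, cell_id),
                              m = max(norm_area), .groups = "drop")
  expect_true(all(abs(by_cell$m - 100) < 1e-12))
  expect_true(is.logical(al$short_side))
})

test_that("group means and SEM follow hand arithmetic", {
  two <- dplyr::bind_rows(
    mk_trace(c(100, 80), cell = 1L),
    mk_trace(c(100, 60), cell = 2L))
  al <- align_at_max(two)
  gm <- group_mean_trace(al)
  expect_equal(gm$mean, c(100, 70))
  expect_equal(gm$sem[2], 10)           # sd(80, 60)/sqrt(2)
  expect_equal(gm$sem[1], 0)
  same <- dplyr::bind_rows(mk_trace(c(50, 100, 70), cell = 1L),
                           mk_trace(c(50, 100, 70), cell = 2L))
  gs <- group_mean_trace(align_at_max(same))
  expect_true(all(gs$sem == 0))
  expect_equal(gs$mean, c(50, 100, 70))
})

test_that("neighbour-class traces stay flat after the peak without noise", {
  spec <- dynamics_spec(noise_sd = 0, rate_cv = 0, seed = 8)
  tr <- simulate_area_traces(make_trace_cohort(1, 6, groups = "neighbour"), spec)
  al <- align_at_max(tr)
  post <- dplyr::filter(al, aligned_t >= 0)
  expect_true(all(abs(post$norm_area - 100) < 1e-9))
})

test_that("configured 2x dilation appears as a 2x pre-peak slope after alignment", {
  spec <- dynamics_spec(noise_sd = 0, rate_cv = 0, seed = 8)
  tr <- simulate_area_traces(
    make_trace_cohort(1, 6, groups = c("deleted", "distant")), spec)
  al <- align_at_max(tr)
  slope_of <- function(g) {
    d <- dplyr::filter(al, group == g, aligned_t %in% c(-3, 0))
    mean_by_t <- tapply(d$norm_area, d$aligned_t, mean)
    (mean_by_t["0"] - mean_by_t["-3"]) / 3
  }
  expect_equal(unname(slope_of("deleted") / slope_of("distant")), 2,
               tolerance = 1e-9)
})

test_that("per-timepoint comparison aggregates to embryos and Bonferroni-corrects", {
  # identical groups: every adjusted p is 1
  base <- simulate_area_traces(make_trace_cohort(5, 4, groups = "control"),
                               dynamics_spec(noise_sd = 0, rate_cv = 0, seed = 2))
  other <- dplyr::mutate(base, group = "distant",
                         cell_id = cell_id + 1000L)
  al <- align_at_max(dplyr::bind_rows(base, other))
  cmp <- compare_groups_per_timepoint(al, "control", "distant")
  expect_true(all(cmp$p_adjusted == 1))
  # a 10 SD offset at every timepoint: all significant
  off <- dplyr::mutate(base, group = "distant", cell_id = cell_id + 1000L,
                       area_px2 = area_px2 * 2)
  al2 <- align_at_max(dplyr::bind_rows(base, off))
  set.seed(31)
  al2 <- dplyr::mutate(al2, norm_area = norm_area +
                         ifelse(group == "distant", 30, 0) +
                         rnorm(dplyr::n(), 0, 0.5))
  cmp2 <- compare_groups_per_timepoint(al2, "control", "distant")
  # fully covered timepoints are decisively significant; sparsely covered
  # tails (2 embryos, Welch df ~ 1) legitimately may not reach it
  full <- cmp2$n_embryos_a >= 5 & cmp2$n_embryos_b >= 5
  expect_true(any(full))
  expect_true(all(cmp2$p_adjusted[full] < 0.001))
  expect_error(compare_groups_per_timepoint(al[al$embryo_id == 1, ],
                                            "control", "distant"),
               "embryos")
})

test_that("retraction percentage is exact and scale-invariant", {
  rec <- tibble::tibble(embryo_id = 1, cell_type = "control",
                        pre_area = c(100, 70, 50), post_area = c(80, 70, 60))
  r <- retraction_percent(rec)
  expect_equal(r$retraction_pct, c(-20, 0, 20))
  r2 <- retraction_percent(dplyr::mutate(rec, pre_area = pre_area * 0.04,
                                         post_area = post_area * 0.04))
  expect_equal(r2$retraction_pct, r$retraction_pct)
  expect_error(retraction_percent(dplyr::mutate(rec, pre_area = 0)),
               "positive")
})

test_that("embryo-level averaging makes the embryo the unit of measure", {
  rec <- tibble::tibble(embryo_id = c(1, 1, 2, 2),
                        cell_type = "EGFP",
                        retraction_pct = c(-10, -30, -20, -20))
  ea <- embryo_level_average(rec)
  expect_equal(ea$retraction_pct, c(-20, -20))
  expect_equal(sd(ea$retraction_pct), 0)
})

test_that("cell-level pooling inflates type-I error; embryo averaging does not", {
  set.seed(77)
  n_rep <- 300
  rej <- vapply(seq_len(n_rep), function(i) {
    g1 <- simulate_ablation_cohort(class_means = c(A = -10), n_embryos = 5,
                                   cells_per_type = 3, sigma_embryo = 5,
                                   sigma_cell = 5, seed = 10000 + i)
    g2 <- simulate_ablation_cohort(class_means = c(A = -10), n_embryos = 5,
                                   cells_per_type = 3, sigma_embryo = 5,
                                   sigma_cell = 5, seed = 20000 + i)
    r1 <- retraction_percent(g1); r2 <- retraction_percent(g2)
    e1 <- embryo_level_average(r1); e2 <- embryo_level_average(r2)
    c(embryo = t.test(e1$retraction_pct, e2$retraction_pct)$p.value < 0.05,
      cell = t.test(r1$retraction_pct, r2$retraction_pct)$p.value < 0.05)
  }, logical(2))
  expect_lt(abs(mean(rej["embryo", ]) - 0.05), 0.035)
  expect_gt(mean(rej["cell", ]), 0.08)
})

test_that("hierarchical ablation simulation matches its configuration", {
  exact <- simulate_ablation_cohort(sigma_embryo = 0, sigma_cell = 0, seed = 1)
  r <- retraction_percent(exact)
  means <- c(control = -20, EGFP = -20, neighbour = -2, distant = -20)
  expect_equal(r$retraction_pct, unname(means[r$cell_type]))
  expect_equal(r$retraction_pct, r$true_retraction_pct)
  # pre with a -20% draw gives post = 0.8 * pre by construction
  expect_equal(sort(unique(round(exact$post_area / exact$pre_area, 10))),
               c(0.8, 0.98))
  # embryo-level ANOVA separates the non-constricting neighbours
  ab <- simulate_ablation_cohort(seed = 42)
  ea <- embryo_level_average(retraction_percent(ab))
  tt <- t.test(ea$retraction_pct[ea$cell_type == "neighbour"],
               ea$retraction_pct[ea$cell_type == "distant"])
  expect_lt(tt$p.value, 0.01)
})

test_that("sample size solves the smallest n meeting the power target", {
  expect_equal(sample_size_two_group(1, 1), 17L)
  # one fewer subject does not reach the target
  expect_lt(power.t.test(n = 16, delta = 1, sd = 1, sig.level = 0.05)$power,
            0.8)
  expect_gte(power.t.test(n = 17, delta = 1, sd = 1, sig.level = 0.05)$power,
             0.8)
  # tiny power target floors at the minimum t-test size
  expect_equal(sample_size_two_group(1, 1, power = 0.001), 2L)
  # quadratic scaling in sd/delta (exact in the normal regime, large n)
  expect_equal(sample_size_two_group(1, 8) / sample_size_two_group(1, 4), 4,
               tolerance = 0.02)
  n2 <- sample_size_two_group(20, 20)
  # monotone in every argument
  expect_gte(sample_size_two_group(20, 25), n2)
  expect_lte(sample_size_two_group(25, 20), n2)
  expect_gte(sample_size_two_group(20, 20, power = 0.9), n2)
  expect_lte(sample_size_two_group(20, 20, alpha = 0.1), n2)
  expect_error(sample_size_two_group(0, 1), "positive")
})
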