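two_square_mask <- function() {
  img <- matrix(0L, 24, 40)
  img[8:17, 6:15] <- 1L
  img[8:17, 16:25] <- 2L
  img
}

test_that("border segments span the shared interface and read uniform intensity", {
  img <- two_square_mask()
  g <- build_neighbour_graph(img, 1)
  segs <- extract_border_segments(img, g, 1)
  expect_equal(nrow(segs), 1)
  idx <- segs$pixels[[1]]
  cc <- ((idx - 1L) %/% nrow(img)) + 1L
  rr <- ((idx - 1L) %% nrow(img)) + 1L
  # the two one-pixel cell bands flanking the interface (2 x 10), plus the
  # four background pixels at the interface ends that lie within the
  # dilation radius of both cells
  expect_true(all(cc %in% c(15, 16)))
  expect_equal(sum(img[idx] > 0), 20L)
  expect_equal(segs$n_pixels, 24L)
  expect_true(all(rr %in% 7:18))
  flat <- matrix(0.37, nrow(img), ncol(img))
  cls <- classes_on_lattice(g, 2, 1L)
  s <- border_intensity_summary(segs, flat, cls)
  expect_equal(s$mean_intensity, 0.37)
})

test_that("border classes map endpoint pairs as specified", {
  expect_equal(as.character(border_class_of("DELETED", "NEIGHBOUR")),
               "EGFP_NEIGHBOUR")
  expect_equal(as.character(border_class_of("NEIGHBOUR", "DELETED")),
               "EGFP_NEIGHBOUR")
  expect_equal(as.character(border_class_of("NEIGHBOUR", "NEIGHBOUR")),
               "NEIGHBOUR_NEIGHBOUR")
  expect_equal(as.character(border_class_of("DISTANT", "DISTANT")),
               "DISTANT_DISTANT")
  expect_equal(as.character(border_class_of("NEIGHBOUR", "DISTANT")), "OTHER")
  expect_equal(as.character(border_class_of("DELETED", "DELETED")), "OTHER")
  expect_equal(as.character(border_class_of("UNCLASSIFIED", "DISTANT")),
               "OTHER")
})

test_that("every graph edge maps to exactly one border class", {
  fx <- hex_fixture()
  n <- nrow(fx$tess$cells)
  cls <- classes_on_lattice(fx$graph, n, sample(seq_len(n), 30))
  m <- setNames(as.character(cls$class), cls$cell_id)
  bc <- border_class_of(m[as.character(fx$graph$a)],
                        m[as.character(fx$graph$b)])
  expect_equal(length(bc), nrow(fx$graph))
  expect_false(any(is.na(bc)))
})

test_that("normalisation rescales the reference border class to 100", {
  segs <- tibble::tibble(a = c(1L, 2L), b = c(2L, 3L),
                         n_pixels = c(4L, 4L),
                         pixels = list(1:4, 5:8))
  ch <- matrix(0, 2, 4)
  ch[1:4] <- 0.5; ch[5:8] <- 0.25
  cls <- tibble::tibble(cell_id = 1:3,
                        class = factor(c("DISTANT", "DISTANT", "NEIGHBOUR"),
                                       levels = c("DELETED", "NEIGHBOUR",
                                                  "DISTANT", "UNCLASSIFIED")))
  s <- border_intensity_summary(segs, ch, cls, normalize_to = "DISTANT_DISTANT")
  expect_equal(s$pct_of_reference[s$border_class == "DISTANT_DISTANT"], 100)
  expect_equal(s$pct_of_reference[s$border_class == "OTHER"], 50)
  expect_error(border_intensity_summary(segs, ch, cls,
                                        normalize_to = "EGFP_NEIGHBOUR"),
               "reference")
})

test_that("configured border-class contrast survives PSF and noise", {
  fx <- hex_fixture()
  n <- nrow(fx$tess$cells)
  ok <- 0L
  n_seeds <- 20L
  for (s in seq_len(n_seeds)) {
    mos <- assign_mosaic(fx$tess, 0.2, seed = 100 + s)
    cls <- classes_on_lattice(fx$graph, n, which(mos$recombined))
    rs <- render_spec(noise_sd = 0.02, psf_sigma = 1,
                      border_class_intensities = c(EGFP_NEIGHBOUR = 0.4,
                                                   NEIGHBOUR_NEIGHBOUR = 0.4,
                                                   DISTANT_DISTANT = 0.8),
                      seed = 200 + s)
    ch <- render_channels(fx$ras$labels, mos, rs, classes = cls,
                          graph = fx$graph)
    segs <- extract_border_segments(fx$ras$labels, fx$graph, 1)
    bs <- border_intensity_summary(segs, ch$myosin, cls)
    dd <- bs$mean_intensity[bs$border_class == "DISTANT_DISTANT"]
    lo <- bs$mean_intensity[bs$border_class %in%
                              c("EGFP_NEIGHBOUR", "NEIGHBOUR_NEIGHBOUR")]
    if (length(dd) == 1 && length(lo) == 2 && all(dd > lo)) ok <- ok + 1L
  }
  expect_gte(ok / n_seeds, 0.95)
})

test_that("cap/cortex split partitions the cell and classifies the trivial patterns", {
  img <- matrix(0L, 20, 20)
  img[3:16, 3:16] <- 1L
  # uniform intensity: ratio exactly 1 classifies as CAP by convention
  u <- cap_cortex_split(img, matrix(0.4, 20, 20))
  expect_equal(as.character(u$pattern), "CAP")
  expect_equal(u$cap_pixels + u$cortex_pixels, sum(img == 1L))
  # signal only on the rim
  rim <- matrix(0, 20, 20)
  interior <- matrix(0L, 20, 20); interior[5:14, 5:14] <- 1L
  rim[img == 1L & interior == 0L] <- 0.9
  expect_equal(as.character(cap_cortex_split(img, rim)$pattern), "CORTICAL")
  # signal only in the interior
  capch <- matrix(0, 20, 20); capch[7:12, 7:12] <- 0.9
  expect_equal(as.character(cap_cortex_split(img, capch)$pattern), "CAP")
  # erosion that removes the whole cell leaves the pattern undefined
  tiny <- matrix(0L, 12, 12); tiny[5:7, 5:7] <- 1L
  flagged <- cap_cortex_split(tiny, matrix(0.5, 12, 12), erosion_r = 4)
  expect_true(is.na(flagged$pattern))
})

test_that("pattern proportions and chi-square separate opposite classes", {
  recs <- tibble::tibble(cell_id = 1:100,
                         pattern = factor(rep(c("CAP", "CORTICAL"), each = 50),
                                          levels = c("CAP", "CORTICAL")))
  cls <- tibble::tibble(cell_id = 1:100,
                        class = factor(rep(c("DELETED", "DISTANT"), each = 50),
                                       levels = c("DELETED", "NEIGHBOUR",
                                                  "DISTANT", "UNCLASSIFIED")))
  pp <- pattern_proportions(recs, cls)
  expect_lt(pp$test$p_value, 1e-10)
  expect_equal(pp$proportions$prop_cap, c(1, 0))
  # identical pattern mixes: statistic 0, p = 1
  recs2 <- tibble::tibble(cell_id = 1:100,
                          pattern = factor(rep(c("CAP", "CORTICAL"), 50),
                                           levels = c("CAP", "CORTICAL")))
  pp2 <- pattern_proportions(recs2, cls)
  expect_equal(pp2$test$statistic, 0)
  expect_equal(pp2$test$p_value, 1)
})

test_that("rendered cap/cortical assignments are recovered through the pipeline", {
  fx <- hex_fixture()
  n <- nrow(fx$tess$cells)
  mos <- assign_mosaic(fx$tess, 0.2, seed = 9)
  cls <- classes_on_lattice(fx$graph, n, which(mos$recombined))
  set.seed(17)
  pat <- ifelse(cls$class == "DELETED", "CORTICAL",
                sample(c("CAP", "CORTICAL"), n, replace = TRUE))
  rs <- render_spec(noise_sd = 0.02, psf_sigma = 0.8,
                    cap_pattern_assignments = setNames(pat, cls$cell_id),
                    seed = 11)
  ch <- render_channels(fx$ras$labels, mos, rs)
  cc <- cap_cortex_split(fx$ras$labels, ch$myosin)
  pp <- pattern_proportions(cc, cls)
  del <- pp$proportions[pp$proportions$class == "DELETED", ]
  oth <- pp$proportions[pp$proportions$class != "DELETED", ]
  expect_lt(del$prop_cap, 0.1)
  expect_true(all(abs(oth$prop_cap - 0.5) < 0.25))
  expect_lt(pp$test$p_value, 0.01)
})
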