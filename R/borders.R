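#' Extract per-edge border pixel sets
#'
#' For every edge of the neighbour graph, collects the pixels over which
#' border-localised signal (e.g. junctional myosin) is read out: the pixels
#' of each cell whose `radius`-dilated footprint overlaps the other cell,
#' plus any background pixels lying between the two within the dilation
#' radius. Border staining read this way is shared between the two adjacent
#' cells, which is why downstream summaries are per *border class* rather
#' than per cell.
#'
#' @param labels Integer label matrix.
#' @param graph `"neighbour_graph"` built from the same mask and radius.
#' @param radius Dilation radius in pixels (default 1).
#' @return Tibble: `a`, `b`, `n_pixels`, `pixels` (list column of linear
#'   indices into `labels`).
#' @export
extract_border_segments <- function(labels, graph, radius = 1) {
  r <- as.integer(radius)
  nr <- nrow(labels); nc <- ncol(labels)
  pix_by_label <- split(seq_along(labels), labels)
  pix_by_label[["0"]] <- NULL
  segs <- purrr::map2(graph$a, graph$b, function(a, b) {
    pa <- pix_by_label[[as.character(a)]]
    pb <- pix_by_label[[as.character(b)]]
    pp <- c(pa, pb)
    rr <- ((pp - 1L) %% nr) + 1L
    cc <- ((pp - 1L) %/% nr) + 1L
    r0 <- max(1L, min(rr) - r); r1 <- min(nr, max(rr) + r)
    c0 <- max(1L, min(cc) - r); c1 <- min(nc, max(cc) + r)
    sub <- labels[r0:r1, c0:c1, drop = FALSE]
    da <- dilate_binary(sub == a, r)
    db <- dilate_binary(sub == b, r)
    hit <- (sub == a & db) | (sub == b & da) | (sub == 0L & da & db)
    w <- which(hit)
    # map back to full-image linear indices
    sr <- ((w - 1L) %% nrow(sub)) + r0
    sc <- ((w - 1L) %/% nrow(sub)) + c0
    (sc - 1L) * nr + sr
  })
  if (any(lengths(segs) == 0)) {
    abort("graph edge with empty border overlap: graph inconsistent with mask/radius")
  }
  tibble(a = graph$a, b = graph$b, n_pixels = lengths(segs), pixels = segs)
}

dilate_binary <- function(mask, r) {
  out <- mask
  for (dr in -r:r) for (dc in -r:r) {
    if (dr == 0 && dc == 0) next
    out <- out | shift_matrix(mask, dr, dc, fill = FALSE)
  }
  out
}

#' Classify a cell-cell border by its endpoint cell classes
#'
#' The three analysed border classes contrast contractile and
#' non-contractile interfaces: `EGFP_NEIGHBOUR` (deleted-neighbour),
#' `NEIGHBOUR_NEIGHBOUR` and `DISTANT_DISTANT`. Every other pair —
#' including any border with an unclassified endpoint — maps to `OTHER`
#' and is excluded from the three-way comparison, since pooling mixed
#' pairs would dilute the contrast.
#'
#' @param class_a,class_b Cell classes of the two endpoints (character or
#'   factor, vectorised).
#' @return Factor with levels `EGFP_NEIGHBOUR`, `NEIGHBOUR_NEIGHBOUR`,
#'   `DISTANT_DISTANT`, `OTHER`.
#' @export
border_class_of <- function(class_a, class_b) {
  a <- as.character(class_a); b <- as.character(class_b)
  out <- rep("OTHER", length(a))
  out[(a == "DELETED" & b == "NEIGHBOUR") | (a == "NEIGHBOUR" & b == "DELETED")] <- "EGFP_NEIGHBOUR"
  out[a == "NEIGHBOUR" & b == "NEIGHBOUR"] <- "NEIGHBOUR_NEIGHBOUR"
  out[a == "DISTANT" & b == "DISTANT"] <- "DISTANT_DISTANT"
  factor(out, levels = c("EGFP_NEIGHBOUR", "NEIGHBOUR_NEIGHBOUR",
                         "DISTANT_DISTANT", "OTHER"))
}

#' Summarise border intensity by border class
#'
#' Computes the mean channel intensity of every border segment, labels each
#' segment with its border class, and averages per class (per embryo when
#' an `embryo_id` column is present). With `normalize_to` set, every
#' embryo's class means are rescaled so the reference class equals 100
#' (the convention of expressing intensity relative to a reference cell
#' population as 100%).
#'
#' @param segments Tibble from [extract_border_segments()].
#' @param channel Numeric intensity matrix.
#' @param classes Tibble from [assign_cell_classes()].
#' @param normalize_to Optional reference border class name.
#' @return Tibble: (`embryo_id`,) `border_class`, `n_segments`,
#'   `mean_intensity` and, under normalisation, `pct_of_reference`.
#' @export
border_intensity_summary <- function(segments, channel, classes,
                                     normalize_to = NULL) {
  cls <- setNames(as.character(classes$class), classes$cell_id)
  seg <- mutate(segments,
                border_class = border_class_of(cls[as.character(.data$a)],
                                               cls[as.character(.data$b)]),
                mean_intensity = purrr::map_dbl(.data$pixels,
                                                ~ mean(channel[.x])))
  grp <- if ("embryo_id" %in% names(seg)) c("embryo_id", "border_class") else "border_class"
  out <- summarise(group_by(seg, across(dplyr::all_of(grp))),
                   n_segments = dplyr::n(),
                   mean_intensity = mean(.data$mean_intensity),
                   .groups = "drop")
  if (!is.null(normalize_to)) {
    norm_one <- function(d) {
      ref <- d$mean_intensity[d$border_class == normalize_to]
      if (length(ref) != 1 || !is.finite(ref)) {
        abort(sprintf("reference class '%s' missing for normalisation", normalize_to))
      }
      mutate(d, pct_of_reference = 100 * .data$mean_intensity / ref)
    }
    out <- if ("embryo_id" %in% names(out)) {
      dplyr::group_modify(group_by(out, .data$embryo_id), ~ norm_one(.x)) |> ungroup()
    } else {
      norm_one(out)
    }
  }
  out
}

#' Split each cell into apical cap and cortical ring
#'
#' Erodes every cell by `erosion_r` pixels (square structuring element,
#' matching the dilation convention of the neighbour graph): the eroded
#' core is the medio-apical *cap*, the removed rim the junctional
#' *cortex* ring. A cell is called `CAP` when the cap/cortex mean-intensity
#' ratio is at least `theta` (default 1; a uniform cell sits exactly on the
#' boundary and classifies as CAP by convention), otherwise `CORTICAL`.
#' Cells whose erosion removes everything are flagged with pattern `NA`.
#'
#' @param labels Integer label matrix.
#' @param channel Numeric intensity matrix (e.g. myosin heavy chain).
#' @param erosion_r Erosion radius in pixels (default 2).
#' @param theta Cap/cortex ratio threshold (default 1).
#' @return Tibble: `cell_id`, `cap_pixels`, `cortex_pixels`, `cap_mean`,
#'   `cortex_mean`, `ratio`, `pattern` (factor `CAP`/`CORTICAL`, `NA` when
#'   undefined).
#' @export
cap_cortex_split <- function(labels, channel, erosion_r = 2, theta = 1) {
  r <- as.integer(erosion_r)
  interior <- matrix(TRUE, nrow(labels), ncol(labels))
  for (dr in -r:r) for (dc in -r:r) {
    if (dr == 0 && dc == 0) next
    interior <- interior & (shift_matrix(labels, dr, dc, fill = -1L) == labels)
  }
  fg <- labels > 0
  lab <- labels[fg]
  capf <- interior[fg]
  v <- channel[fg]
  ids <- sort(unique(lab))
  f <- factor(lab, levels = ids)
  cap_n <- tapply(capf, f, sum)
  tot_n <- tabulate(f)
  cap_sum <- tapply(v * capf, f, sum)
  tot_sum <- tapply(v, f, sum)
  cap_mean <- ifelse(cap_n > 0, cap_sum / cap_n, NA_real_)
  ring_n <- tot_n - cap_n
  ring_mean <- ifelse(ring_n > 0, (tot_sum - cap_sum) / ring_n, NA_real_)
  ratio <- cap_mean / ring_mean
  # tolerance so the uniform-intensity boundary case (ratio exactly 1 up to
  # floating-point summation order) classifies as CAP at theta = 1
  pattern <- ifelse(is.na(ratio), NA_character_,
                    ifelse(ratio >= theta - 1e-9, "CAP", "CORTICAL"))
  tibble(cell_id = ids,
         cap_pixels = as.integer(cap_n), cortex_pixels = as.integer(ring_n),
         cap_mean = unname(cap_mean), cortex_mean = unname(ring_mean),
         ratio = unname(ratio),
         pattern = factor(pattern, levels = c("CAP", "CORTICAL")))
}

#' Cap/cortical pattern proportions by cell class, with chi-square test
#'
#' @param records Tibble from [cap_cortex_split()].
#' @param classes Tibble from [assign_cell_classes()]; classes with no
#'   patterned record are excluded with a warning.
#' @return List with `proportions` (tibble: `class`, `n`, `prop_cap`,
#'   `prop_cortical`) and `test` (tibble: `statistic`, `df`, `p_value`).
#' @export
pattern_proportions <- function(records, classes) {
  d <- inner_join(records, select(classes, "cell_id", "class"), by = "cell_id")
  d <- filter(d, !is.na(.data$pattern))
  d$class <- droplevels(factor(d$class))
  empty <- setdiff(levels(factor(classes$class)), levels(d$class))
  if (length(empty)) warn(paste("classes with no patterned cells excluded:",
                                paste(empty, collapse = ", ")))
  if (nlevels(d$class) < 2) abort("need >= 2 classes with patterned cells")
  tab <- table(d$class, d$pattern)
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  props <- summarise(group_by(d, .data$class),
                     n = dplyr::n(),
                     prop_cap = mean(.data$pattern == "CAP"),
                     prop_cortical = mean(.data$pattern == "CORTICAL"),
                     .groups = "drop")
  list(proportions = props,
       test = tibble(statistic = unname(ht$statistic),
                     df = unname(ht$parameter), p_value = ht$p.value))
}
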