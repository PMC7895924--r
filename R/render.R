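#' Specify a synthetic fluorescence render
#'
#' Parameters for turning a label image plus mosaic assignment into
#' membrane-reporter channels. The reporter geometry emulates a membrane
#' tdTomato / membrane EGFP switch: every cell carries membrane signal in
#' the tdTomato channel, while only recombined cells carry membrane EGFP.
#' Real recombined cells additionally show diffuse cytoplasmic EGFP, which
#' is what makes an intracellular pixel-fraction threshold workable; the
#' renderer reproduces this with a configurable interior fill (default 0.15
#' of the membrane level).
#'
#' @param membrane_width Membrane half-thickness in pixels (Chebyshev
#'   distance to a differing label; default 1 gives a ~2 px wall).
#' @param egfp_level,tdtom_level Membrane intensities in \[0, 1\].
#' @param interior_fill Cytoplasmic EGFP as a fraction of `egfp_level`.
#' @param noise_sd Additive Gaussian noise SD (intensity units).
#' @param psf_sigma Gaussian blur sigma in pixels (0 = none).
#' @param border_class_intensities Optional named vector of myosin-channel
#'   means per border class (names among `EGFP_NEIGHBOUR`,
#'   `NEIGHBOUR_NEIGHBOUR`, `DISTANT_DISTANT`, `OTHER`).
#' @param cap_pattern_assignments Optional per-cell character vector
#'   (`"CAP"`/`"CORTICAL"`, names or order = cell ids) for the myosin
#'   channel.
#' @param myosin_base Background myosin intensity.
#' @param myosin_level Intensity of the patterned myosin compartment.
#' @param seed Integer seed for the noise stream.
#' @return A list of class `"render_spec"`.
#' @export
render_spec <- function(membrane_width = 1, egfp_level = 0.8,
                        tdtom_level = 0.8, interior_fill = 0.15,
                        noise_sd = 0.02, psf_sigma = 1,
                        border_class_intensities = NULL,
                        cap_pattern_assignments = NULL,
                        myosin_base = 0.1, myosin_level = 0.6,
                        seed = 1L) {
  stopifnot_scalar_prob(egfp_level, "egfp_level")
  stopifnot_scalar_prob(tdtom_level, "tdtom_level")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  structure(list(membrane_width = as.integer(membrane_width),
                 egfp_level = egfp_level, tdtom_level = tdtom_level,
                 interior_fill = interior_fill, noise_sd = noise_sd,
                 psf_sigma = psf_sigma,
                 border_class_intensities = border_class_intensities,
                 cap_pattern_assignments = cap_pattern_assignments,
                 myosin_base = myosin_base, myosin_level = myosin_level,
                 seed = as.integer(seed)),
            class = "render_spec")
}

#' Render fluorescence channels from a label image and mosaic
#'
#' @param labels Integer label matrix.
#' @param mosaic Tibble from [assign_mosaic()] (`cell_id`, `recombined`).
#' @param spec A [render_spec()].
#' @param classes,graph Optional [assign_cell_classes()] /
#'   [build_neighbour_graph()] outputs; required only when
#'   `spec$border_class_intensities` is set (the myosin channel reads
#'   border classes from them).
#' @return Named list of numeric matrices in \[0, 1\]: `tdtom`, `egfp`,
#'   and `myosin` when any myosin option is configured.
#' @export
render_channels <- function(labels, mosaic, spec, classes = NULL, graph = NULL) {
  stopifnot(inherits(spec, "render_spec"))
  w <- spec$membrane_width
  membrane <- matrix(FALSE, nrow(labels), ncol(labels))
  for (dr in -w:w) for (dc in -w:w) {
    if (dr == 0 && dc == 0) next
    membrane <- membrane | (shift_matrix(labels, dr, dc, fill = 0L) != labels)
  }
  membrane <- membrane & labels > 0

  rec <- logical(max(labels) + 1L)           # index by label + 1
  rec[mosaic$cell_id + 1L] <- mosaic$recombined
  is_rec <- matrix(rec[labels + 1L], nrow(labels))

  tdtom <- ifelse(membrane, spec$tdtom_level, 0)
  egfp <- matrix(0, nrow(labels), ncol(labels))
  egfp[membrane & is_rec] <- spec$egfp_level
  egfp[!membrane & is_rec & labels > 0] <- spec$interior_fill * spec$egfp_level

  out <- list(tdtom = tdtom, egfp = egfp)

  want_myosin <- !is.null(spec$border_class_intensities) ||
    !is.null(spec$cap_pattern_assignments)
  if (want_myosin) {
    myo <- matrix(spec$myosin_base, nrow(labels), ncol(labels))
    if (!is.null(spec$cap_pattern_assignments)) {
      pat <- spec$cap_pattern_assignments
      ids <- if (!is.null(names(pat))) as.integer(names(pat)) else seq_along(pat)
      capv <- logical(max(labels) + 1L); corv <- logical(max(labels) + 1L)
      capv[ids + 1L] <- pat == "CAP"
      corv[ids + 1L] <- pat == "CORTICAL"
      cap_cell <- matrix(capv[labels + 1L], nrow(labels))
      cor_cell <- matrix(corv[labels + 1L], nrow(labels))
      myo[cap_cell & !membrane & labels > 0] <- spec$myosin_level
      myo[cor_cell & membrane] <- spec$myosin_level
    }
    if (!is.null(spec$border_class_intensities)) {
      if (is.null(classes) || is.null(graph)) {
        abort("border_class_intensities requires `classes` and `graph`")
      }
      segs <- extract_border_segments(labels, graph, radius = max(1L, w))
      cls <- setNames(as.character(classes$class), classes$cell_id)
      bc <- border_class_of(cls[as.character(segs$a)], cls[as.character(segs$b)])
      lv <- spec$border_class_intensities
      for (k in seq_len(nrow(segs))) {
        val <- unname(lv[as.character(bc[k])])
        if (length(val) == 1 && !is.na(val)) myo[segs$pixels[[k]]] <- val
      }
    }
    out$myosin <- myo
  }

  out <- purrr::map(out, function(ch) {
    if (spec$psf_sigma > 0) ch <- EBImage::gblur(ch, sigma = spec$psf_sigma)
    ch
  })
  if (spec$noise_sd > 0) {
    out <- with_seed(spec$seed, purrr::map(out, function(ch) {
      ch + rnorm(length(ch), 0, spec$noise_sd)
    }))
  }
  purrr::map(out, function(ch) {
    ch[ch < 0] <- 0; ch[ch > 1] <- 1
    ch
  })
}
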