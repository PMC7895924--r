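#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy and summarise fitted mosaictile objects
#'
#' Broom-style methods: `tidy()` returns the per-component table of an
#' object (per-cell table of a tessellation, term table of a Lewis fit);
#' `glance()` returns a one-row model summary.
#'
#' @param x A fitted object (`lewis_fit`, `epi_tessellation`).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.lewis_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble(term = c("intercept", "degree"),
         estimate = c(x$intercept, x$slope),
         std_error = s[, "Std. Error"],
         p_value = s[, "Pr(>|t|)"])
}

#' @rdname tidy.lewis_fit
#' @export
glance.lewis_fit <- function(x, ...) {
  tibble(pearson_r = x$pearson_r, r_squared = x$pearson_r^2,
         p_value = x$p_value, n_cells = x$n_cells,
         slope = x$slope, intercept = x$intercept)
}
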