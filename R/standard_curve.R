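#' Fit a qPCR standard curve
#'
#' Fits the linear calibration `Ct = intercept + slope * log10(concentration)`
#' by ordinary least squares on a dilution series of a synthetic miRNA mimic.
#' The amplification efficiency is derived from the slope as
#' `10^(-1/slope) - 1`; a perfect doubling per cycle gives slope
#' `-1/log10(2) ~ -3.32` and efficiency 1.
#'
#' @param dilution_series Data frame with one row per calibration point.
#'   Must contain a concentration column (`concentration` or
#'   `concentration_fmol_per_l`, in fmol/L, all > 0) and a `ct` column
#'   (cycles, all finite).
#' @param mirna Optional assay identifier stored with the curve.
#'
#' @return An object of class `standard_curve`: a list with elements
#'   `mirna`, `slope` (cycles per log10 fmol/L), `intercept` (cycles, the
#'   predicted Ct at 1 fmol/L), `r_squared`, `efficiency` and `n`.
#' @examples
#' ds <- data.frame(concentration = 10^(4:2), ct = c(20, 23.3219, 26.6439))
#' fit_standard_curve(ds, "miR-21-5p")
#' @export
fit_standard_curve <- function(dilution_series, mirna = NULL) {
  conc_col <- intersect(
    c("concentration", "concentration_fmol_per_l"), names(dilution_series)
  )[1]
  if (is.na(conc_col) || !"ct" %in% names(dilution_series)) {
    abort("dilution_series needs columns 'concentration' (or 'concentration_fmol_per_l') and 'ct'")
  }
  conc <- dilution_series[[conc_col]]
  ct <- dilution_series$ct
  if (any(!is.finite(conc)) || any(conc <= 0)) {
    abort("all concentrations must be finite and > 0")
  }
  if (any(!is.finite(ct))) {
    abort("all Ct values must be finite")
  }
  if (length(unique(conc)) < 2) {
    abort("standard curve needs at least 2 distinct concentrations")
  }

  fit <- lm(ct ~ log10(conc))
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((ct - mean(ct))^2)
  r_squared <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1

  if (slope >= 0) {
    warn("standard curve slope is non-negative; Ct should fall as concentration rises")
  }
  structure(
    list(
      mirna = mirna,
      slope = slope,
      intercept = intercept,
      r_squared = r_squared,
      efficiency = 10^(-1 / slope) - 1,
      n = length(ct)
    ),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(
    "<standard_curve>", if (!is.null(x$mirna)) x$mirna else "",
    sprintf(
      "\n  slope %.4f cycles/log10(fmol/L), intercept %.4f, R^2 %.4f, efficiency %.3f (n = %d)\n",
      x$slope, x$intercept, x$r_squared, x$efficiency, x$n
    )
  )
  invisible(x)
}

#' @method tidy standard_curve
#' @export
tidy.standard_curve <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @method glance standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble::tibble(
    mirna = x$mirna %||% NA_character_,
    slope = x$slope,
    intercept = x$intercept,
    r_squared = x$r_squared,
    efficiency = x$efficiency,
    n = x$n
  )
}

#' Predicted Ct for a known concentration
#'
#' @param curve A [fit_standard_curve()] object.
#' @param concentration Concentration(s) in fmol/L (> 0).
#' @return Predicted Ct values (cycles).
#' @export
predict_ct <- function(curve, concentration) {
  stopifnot(inherits(curve, "standard_curve"))
  if (any(concentration <= 0, na.rm = TRUE)) {
    abort("concentration must be > 0")
  }
  curve$intercept + curve$slope * log10(concentration)
}

#' Convert Ct values to absolute concentration
#'
#' Inverts the standard curve: `10^((ct - intercept) / slope)`. Undetected
#' cells (`NA`) stay undetected.
#'
#' @param ct Ct values in cycles; `NA` means undetected.
#' @param curve A [fit_standard_curve()] object with negative slope.
#' @return Concentrations in fmol/L, `NA` where undetected.
#' @export
ct_to_concentration <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope >= 0) {
    abort("standard curve slope must be negative")
  }
  10^((ct - curve$intercept) / curve$slope)
}

#' @method autoplot standard_curve
#' @export
autoplot.standard_curve <- function(object, ...) {
  lg <- seq(0, 6, length.out = 50)
  grid <- tibble::tibble(
    log10_concentration = lg,
    ct = object$intercept + object$slope * lg
  )
  ggplot2::ggplot(grid, ggplot2::aes(.data$log10_concentration, .data$ct)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "log10 concentration (fmol/L)", y = "Ct (cycles)",
      title = object$mirna %||% "standard curve",
      subtitle = sprintf(
        "slope %.3f, efficiency %.2f, R² %.3f",
        object$slope, object$efficiency, object$r_squared
      )
    )
}
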