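#' Unit conversion helpers
#'
#' All internal computation uses SI units (m, s, Pa, m^3/s). Clinical inputs
#' are usually quoted in L/min and mmHg; these helpers convert exactly at the
#' configuration boundary.
#'
#' @param x numeric value(s) in the clinical unit.
#' @return numeric value(s) in the SI unit (m^3/s for `lpm()`, Pa for
#'   `mmhg()`), or back in the clinical unit for the inverse helpers.
#' @examples
#' lpm(5)            # 5 L/min in m^3/s
#' as_lpm(lpm(5))    # round trip
#' mmhg(120)         # 120 mmHg in Pa
#' @name units
NULL

# exact conversion constants
.LPM_TO_M3S <- 1e-3 / 60
.MMHG_TO_PA <- 133.322387415

#' @rdname units
#' @export
lpm <- function(x) x * .LPM_TO_M3S

#' @rdname units
#' @export
as_lpm <- function(x) x / .LPM_TO_M3S

#' @rdname units
#' @export
mmhg <- function(x) x * .MMHG_TO_PA

#' @rdname units
#' @export
as_mmhg <- function(x) x / .MMHG_TO_PA

#' Round half away from zero
#'
#' Rounding convention used when rendering percentages to one decimal, so that
#' e.g. a variation of -0.45 percentage points prints as -0.5 rather than
#' banker's-rounded -0.4.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits to keep.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# trapezoidal integral of y(t) over a (possibly non-uniform) grid
trapz <- function(t, y) {
  n <- length(t)
  if (n < 2L) stop("trapezoidal integration needs at least 2 samples")
  sum((y[-1] + y[-n]) * diff(t)) / 2
}

# trapezoidal mean over the grid span
trapz_mean <- function(t, y) trapz(t, y) / (t[length(t)] - t[1])
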