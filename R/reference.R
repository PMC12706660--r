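#' Reference flow-division table
#'
#' The bundled clinical-CFD reference table of flow divisions in the aortic
#' branches for an adult patient at 5 L/min total perfusion: the baseline
#' share of each of the 15 branch outlets and the shares/variations under
#' femoral (FA) and axillary (AA) LVAD perfusion at 40% and 60% pump
#' support. The baseline column (which sums to exactly 100.0) provides the
#' default calibration targets; the scenario columns are used as worked-
#' example inputs for the variation and relative-change arithmetic.
#'
#' @return data frame with columns `outlet`, `baseline`, and
#'   `{fa40,aa40,fa60,aa60}` share and `_variation` columns, all in percent
#'   (variations in percentage points).
#' @export
reference_flow_divisions <- function() {
  path <- system.file("extdata", "reference_flow_divisions.tsv",
                      package = "lvadflow", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Reference shares for one scenario
#'
#' @param scenario one of `"baseline"`, `"fa40"`, `"aa40"`, `"fa60"`,
#'   `"aa60"`.
#' @return named numeric vector, outlet name -> share in percent.
#' @export
reference_shares <- function(scenario = c("baseline", "fa40", "aa40",
                                          "fa60", "aa60")) {
  scenario <- match.arg(scenario)
  ref <- reference_flow_divisions()
  stats::setNames(ref[[scenario]], ref$outlet)
}

#' Default calibration targets
#'
#' The baseline reference flow divisions with 120/80 mmHg pressure targets
#' at a cardiac output of 5 L/min.
#'
#' @inheritParams calibration_targets
#' @return a [calibration_targets()] object.
#' @export
default_targets <- function(p_sys = mmhg(120), p_dia = mmhg(80),
                            co = lpm(5), pv = 0) {
  calibration_targets(reference_shares("baseline"),
                      p_sys = p_sys, p_dia = p_dia, co = co, pv = pv)
}
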