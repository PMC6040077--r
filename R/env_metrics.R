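# Closed-form environmental computations: N:P ratio and flow-cytometry
# cell concentration.

#' Round half away from zero
#'
#' Reporting convention for printed ratios (R's `round()` rounds half
#' to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 2) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' N:P ratio from total N and total P
#'
#' @param total_n_uM Total nitrogen (micromolar).
#' @param total_p_uM Total phosphorus (micromolar, > 0).
#' @param digits Reporting precision (half-away-from-zero rounding);
#'   `NULL` for the raw ratio.
#' @return Ratio(s).
#' @export
np_ratio <- function(total_n_uM, total_p_uM, digits = 2) {
  if (any(total_p_uM <= 0)) stop("total_p_uM must be > 0")
  r <- total_n_uM / total_p_uM
  if (is.null(digits)) r else round_half_up(r, digits)
}

#' Flow-cytometry cell concentration
#'
#' `N = n * 1000 / (q * t)`: events counted, flow rate in microlitres
#' per minute, acquisition time in minutes; the result is cells per
#' millilitre.
#'
#' @param n_events Events counted (>= 0).
#' @param flow_rate_uL_per_min Flow rate (> 0).
#' @param duration_min Acquisition time in minutes (> 0); use
#'   `duration_s` instead for seconds.
#' @param duration_s Acquisition time in seconds (converted to
#'   minutes).
#' @return Cells per mL.
#' @export
cytometry_concentration <- function(n_events, flow_rate_uL_per_min,
                                    duration_min = NULL,
                                    duration_s = NULL) {
  if (is.null(duration_min) && is.null(duration_s))
    stop("supply duration_min or duration_s")
  if (is.null(duration_min)) duration_min <- duration_s / 60
  if (any(n_events < 0)) stop("n_events must be >= 0")
  if (any(flow_rate_uL_per_min <= 0) || any(duration_min <= 0))
    stop("flow rate and duration must be > 0")
  n_events * 1000 / (flow_rate_uL_per_min * duration_min)
}

#' Bundled water-column nutrient table
#'
#' Nutrient and sequencing summary for a nine-sample Mediterranean
#' water-column survey (six stratified photic depths, one 1000 m
#' aphotic sample, two winter mixed depths), including the printed
#' N:P ratios for cross-checking.
#'
#' @return Data frame, one row per sample.
#' @export
bundled_nutrients <- function() {
  read_nutrients(system.file("extdata", "med_water_column_nutrients.tsv",
                             package = "stratiprof", mustWork = TRUE))
}
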