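#' Global upscaling scenario for nitrification-derived N2O
#'
#' Bundles the inputs of the global emission-scenario arithmetic: the
#' baseline estuarine-plus-coastal N2O emission, the fraction of it
#' attributable to nitrifiers, the fractional response range of
#' nitrification-derived N2O production to the projected mean acidification
#' (a 0.21 pH-unit decrease), and the total anthropogenic N2O emission used
#' as the denominator of the share calculation.
#'
#' There is no authoritative default for `baseline_emission_tg`: it must be
#' supplied. [reconstructed_baseline_tg()] documents a synthetic placeholder
#' range derived by inverting the headline emission-increase figures.
#'
#' @param baseline_emission_tg Global estuarine + coastal N2O emission
#'   (Tg N2O-N yr^-1), >= 0. Required.
#' @param nitrifier_share Fraction of the baseline from nitrification, in
#'   `[0, 1]` (default 0.5).
#' @param response_low,response_high Fractional increase of
#'   nitrification-derived N2O at the scenario acidification (e.g. 0.095
#'   and 0.275); `response_low <= response_high`.
#' @param anthropogenic_total_tg Total anthropogenic N2O emission
#'   (Tg N2O-N yr^-1), > 0 (default 6.9).
#' @return A list of class `upscale_scenario`.
#' @export
upscale_scenario <- function(baseline_emission_tg,
                             nitrifier_share = 0.5,
                             response_low = 0.095,
                             response_high = 0.275,
                             anthropogenic_total_tg = 6.9) {
  if (baseline_emission_tg < 0) {
    stop("baseline_emission_tg must be >= 0", call. = FALSE)
  }
  if (nitrifier_share < 0 || nitrifier_share > 1) {
    stop("nitrifier_share must lie in [0, 1]", call. = FALSE)
  }
  if (response_low < 0 || response_high < response_low) {
    stop("need 0 <= response_low <= response_high", call. = FALSE)
  }
  if (anthropogenic_total_tg <= 0) {
    stop("anthropogenic_total_tg must be positive", call. = FALSE)
  }
  structure(
    list(baseline_emission_tg = baseline_emission_tg,
         nitrifier_share = nitrifier_share,
         response_low = response_low, response_high = response_high,
         anthropogenic_total_tg = anthropogenic_total_tg),
    class = "upscale_scenario"
  )
}

#' Reconstructed baseline emission placeholder
#'
#' A synthetic stand-in for the global estuarine + coastal N2O baseline:
#' obtained by algebraically inverting an emission-increase range of
#' 0.05-0.15 Tg N2O-N yr^-1 under a nitrifier share of 0.5 and a fractional
#' response of 0.095-0.275, which implies a baseline of about 1.05-1.09 Tg
#' N2O-N yr^-1. This is a reconstruction, not a sourced inventory value;
#' use a literature inventory figure for real upscaling.
#'
#' @return Named numeric vector with `low`, `high`, `mid` (Tg N2O-N yr^-1).
#' @export
reconstructed_baseline_tg <- function() {
  low <- 0.05 / (0.5 * 0.095)
  high <- 0.15 / (0.5 * 0.275)
  c(low = min(low, high), high = max(low, high), mid = (low + high) / 2)
}

#' Emission increase under an acidification scenario
#'
#' `increase = baseline x nitrifier_share x response`, evaluated at the low
#' and high ends of the response range.
#'
#' @param scenario An [upscale_scenario()].
#' @return Named numeric vector `c(low, high)` in Tg N2O-N yr^-1.
#' @examples
#' sc <- upscale_scenario(baseline_emission_tg = 1.07)
#' emission_increase(sc)
#' @export
emission_increase <- function(scenario) {
  stopifnot(inherits(scenario, "upscale_scenario"))
  c(low = scenario$baseline_emission_tg * scenario$nitrifier_share *
      scenario$response_low,
    high = scenario$baseline_emission_tg * scenario$nitrifier_share *
      scenario$response_high)
}

# round-half-up to `digits` decimals (base round() is round-half-even)
round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Share of anthropogenic N2O emissions
#'
#' Expresses an emission increase as a percentage of the total anthropogenic
#' N2O emission, rounded half-up to one decimal (the convention of the
#' headline range this arithmetic supports).
#'
#' @param increase Emission increase(s) (Tg N2O-N yr^-1); vectorised, so a
#'   `c(low, high)` pair from [emission_increase()] works directly.
#' @param anthropogenic_total_tg Total anthropogenic emission
#'   (Tg N2O-N yr^-1), > 0.
#' @return Percent share(s), one decimal.
#' @examples
#' share_of_anthropogenic(c(0.05, 0.15), 6.9)  # 0.7 and 2.2
#' @export
share_of_anthropogenic <- function(increase, anthropogenic_total_tg = 6.9) {
  if (anthropogenic_total_tg <= 0) {
    stop("anthropogenic_total_tg must be positive", call. = FALSE)
  }
  if (any(increase < 0)) stop("increase must be >= 0", call. = FALSE)
  round_half_up(100 * increase / anthropogenic_total_tg, 1)
}
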