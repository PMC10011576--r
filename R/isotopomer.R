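#' N2O isotopomer signature from site-specific delta values
#'
#' Builds the full natural-abundance isotopic signature of an N2O sample
#' from the central (alpha) and terminal (beta) nitrogen delta values:
#' site preference `SP = d15N_alpha - d15N_beta` and bulk
#' `d15N_bulk = (d15N_alpha + d15N_beta) / 2`. SP is the
#' pathway-diagnostic quantity; d18O is carried as data but not modelled.
#'
#' @param d15n_alpha delta15N of the central N atom (permil).
#' @param d15n_beta delta15N of the terminal N atom (permil).
#' @param d18o delta18O of the N2O (permil), optional.
#' @return A one-row data.frame (class `isotopomer_signature`) with columns
#'   `d15n_alpha`, `d15n_beta`, `d15n_bulk`, `d18o`, `sp`.
#' @examples
#' n2o_signature(30, 0, 40)  # SP = 30, bulk = 15
#' @export
n2o_signature <- function(d15n_alpha, d15n_beta, d18o = NA_real_) {
  stopifnot(is.finite(d15n_alpha), is.finite(d15n_beta))
  out <- data.frame(
    d15n_alpha = d15n_alpha, d15n_beta = d15n_beta,
    d15n_bulk = (d15n_alpha + d15n_beta) / 2,
    d18o = d18o, sp = d15n_alpha - d15n_beta
  )
  class(out) <- c("isotopomer_signature", "data.frame")
  out
}

#' Pathway endmembers for SP-based source partitioning
#'
#' Site-preference endmembers of the two N2O source classes resolved by the
#' mixing model: production via NH2OH oxidation (high SP) and NO2- reduction
#' (nitrifier denitrification plus heterotrophic denitrification, low SP).
#'
#' The shipped defaults (+30 permil and 0 permil, sd 3 permil each) are
#' literature-typical class values for culture-derived endmembers and are
#' configuration, not authoritative constants: site-specific studies should
#' supply their own calibrated values.
#'
#' @param sp_production Mean SP of the NH2OH-oxidation pathway (permil).
#' @param sp_production_sd Its standard deviation (permil), >= 0.
#' @param sp_reduction Mean SP of the NO2--reduction pathways (permil).
#' @param sp_reduction_sd Its standard deviation (permil), >= 0.
#' @return A list of class `pathway_endmembers`.
#' @export
pathway_endmembers <- function(sp_production = 30, sp_production_sd = 3,
                               sp_reduction = 0, sp_reduction_sd = 3) {
  if (sp_production == sp_reduction) {
    stop("endmember SP values must be distinct", call. = FALSE)
  }
  if (sp_production_sd < 0 || sp_reduction_sd < 0) {
    stop("endmember standard deviations must be >= 0", call. = FALSE)
  }
  structure(
    list(sp_production = sp_production, sp_production_sd = sp_production_sd,
         sp_reduction = sp_reduction, sp_reduction_sd = sp_reduction_sd),
    class = "pathway_endmembers"
  )
}

#' Fraction of N2O from NO2- reduction by two-endmember SP mixing
#'
#' Linear two-endmember mixing on the site-preference axis:
#' \deqn{f = \frac{SP_{prod} - SP_{sample}}{SP_{prod} - SP_{red}}}
#' The estimate is clipped to `[0, 1]`; a sample outside the endmember
#' envelope is flagged via the `clipped` field rather than silently
#' truncated.
#'
#' @param sp_sample Measured SP of the emitted N2O (permil); vectorised.
#' @param endmembers A [pathway_endmembers()] object.
#' @return A data.frame with columns `f` (clipped fraction in `[0, 1]`),
#'   `f_raw` (unclipped), and `clipped` (logical).
#' @examples
#' em <- pathway_endmembers()
#' fraction_from_reduction(15, em)$f  # 0.5 at the midpoint
#' @export
fraction_from_reduction <- function(sp_sample, endmembers = pathway_endmembers()) {
  stopifnot(inherits(endmembers, "pathway_endmembers"))
  f_raw <- (endmembers$sp_production - sp_sample) /
    (endmembers$sp_production - endmembers$sp_reduction)
  f <- pmin(1, pmax(0, f_raw))
  data.frame(f = f, f_raw = f_raw, clipped = f != f_raw)
}

#' Monte-Carlo uncertainty for the SP mixing fraction
#'
#' Propagates measurement and endmember uncertainty through the mixing
#' model: normal draws for the sample SP and both endmembers, per-draw
#' mixing with clipping to `[0, 1]`, then a summary over draws. Reproducible
#' for a fixed seed; clip events are counted and reported.
#'
#' @param sp_sample Measured SP (permil).
#' @param sp_sample_sd Its standard deviation (permil), >= 0.
#' @param endmembers A [pathway_endmembers()] object.
#' @param n_draws Number of Monte-Carlo draws, >= 100.
#' @param seed Integer seed (required, for reproducibility).
#' @return A list with `mean`, `sd`, `q025`, `q975`, `n_clipped`, `n_draws`.
#' @examples
#' mc_fraction(20, 2, n_draws = 1000, seed = 1)
#' @export
mc_fraction <- function(sp_sample, sp_sample_sd = 0,
                        endmembers = pathway_endmembers(),
                        n_draws = 10000, seed) {
  stopifnot(inherits(endmembers, "pathway_endmembers"))
  if (n_draws < 100) stop("n_draws must be >= 100", call. = FALSE)
  if (sp_sample_sd < 0) stop("sp_sample_sd must be >= 0", call. = FALSE)
  if (missing(seed)) stop("a seed is required for reproducibility",
                          call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sp <- stats::rnorm(n_draws, sp_sample, sp_sample_sd)
  prod <- stats::rnorm(n_draws, endmembers$sp_production,
                       endmembers$sp_production_sd)
  red <- stats::rnorm(n_draws, endmembers$sp_reduction,
                      endmembers$sp_reduction_sd)
  f_raw <- (prod - sp) / (prod - red)
  f <- pmin(1, pmax(0, f_raw))
  q <- unname(stats::quantile(f, c(0.025, 0.975)))
  list(mean = mean(f), sd = stats::sd(f), q025 = q[1], q975 = q[2],
       n_clipped = sum(f != f_raw), n_draws = n_draws)
}
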