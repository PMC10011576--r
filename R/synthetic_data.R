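#' Configuration for a synthetic tracer incubation
#'
#' Defines the ground truth and design of a simulated 15N-tracer incubation.
#' Defaults mirror a typical estuarine acidification experiment: 4 L
#' vessels sampled at the start and end of a 24 h run, ambient NH4+ around
#' 10 umol L^-1 with tracer added below 20% of ambient (F about 0.167), a
#' true nitrification rate of 100 nmol L^-1 h^-1, a true N2O production
#' rate of 5 pmol N2O-N L^-1 h^-1, and 5% multiplicative measurement noise.
#'
#' @param true_nitrification_rate True rate (nmol L^-1 h^-1), >= 0.
#' @param true_n2o_rate True N2O production rate (pmol N2O-N L^-1 h^-1,
#'   counting N atoms), >= 0.
#' @param pairing_model `"binomial"` (both N atoms drawn independently from
#'   the labelled NH4+ pool: p45 = 2F(1-F), p46 = F^2) or `"single_label"`
#'   (at most one labelled atom: p45 = F, p46 = 0).
#' @param ambient_nh4 Ambient 14NH4+ (umol L^-1).
#' @param added_15nh4 Added 15NH4+ tracer (umol L^-1).
#' @param nox0 Initial NOx- concentration (umol L^-1).
#' @param r15_init Initial 15N atom fraction of the NOx- pool; defaults to
#'   natural abundance 0.00366.
#' @param volume Water sample volume (L).
#' @param sample_times Sampling times (hours), strictly increasing from 0.
#' @param noise_cv Multiplicative Gaussian noise CV per observation, >= 0.
#' @param seed Integer seed, or `NULL` for the current RNG stream.
#' @return A list of class `sim_config`. `F` is derived from the ammonium
#'   pool via [atom_fraction()].
#' @export
sim_config <- function(true_nitrification_rate = 100,
                       true_n2o_rate = 5,
                       pairing_model = c("binomial", "single_label"),
                       ambient_nh4 = 10, added_15nh4 = 2,
                       nox0 = 10, r15_init = 0.00366,
                       volume = 4, sample_times = c(0, 24),
                       noise_cv = 0.05, seed = NULL) {
  pairing_model <- match.arg(pairing_model)
  if (true_nitrification_rate < 0 || true_n2o_rate < 0) {
    stop("true rates must be >= 0", call. = FALSE)
  }
  if (length(sample_times) < 2L || sample_times[1] != 0 ||
      is.unsorted(sample_times, strictly = TRUE)) {
    stop("sample_times must be strictly increasing and start at 0",
         call. = FALSE)
  }
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (r15_init < 0 || r15_init > 1) {
    stop("r15_init must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(true_nitrification_rate = true_nitrification_rate,
         true_n2o_rate = true_n2o_rate,
         pairing_model = pairing_model,
         ambient_nh4 = ambient_nh4, added_15nh4 = added_15nh4,
         F = atom_fraction(ambient_nh4, added_15nh4),
         nox0 = nox0, r15_init = r15_init,
         volume = volume, sample_times = sample_times,
         noise_cv = noise_cv, seed = seed),
    class = "sim_config"
  )
}

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a 15N-tracer incubation time series
#'
#' Forward-simulates the observables of one incubation vessel under the
#' model the rate estimators assume: the NOx- pool grows linearly at the
#' true nitrification rate with the labelled fraction of new NOx- equal to
#' the (constant) tracer atom fraction F, so
#' `r15(t) = (r15_0 nox_0 + R F t) / (nox_0 + R t)`; N2O molecules are
#' produced at half the N-atom rate and split into mass-45/46 isotopologues
#' by the pairing model. Multiplicative Gaussian noise with the configured
#' CV is applied independently to every observation; at `noise_cv = 0` the
#' series is exact, so the endpoint estimators recover the generating rates
#' to machine precision.
#'
#' @param config A [sim_config()].
#' @param vessel_id,treatment Labels stamped on the output rows.
#' @return A data.frame with columns `vessel_id`, `treatment`, `time_h`,
#'   `nox_umol_L`, `r15_nox`, `n2o45_pmol`, `n2o46_pmol`, carrying the
#'   generating truth in `attr(, "truth")`.
#' @examples
#' sim <- simulate_incubation(sim_config(noise_cv = 0))
#' nitrification_rate(sim$time_h, sim$nox_umol_L, sim$r15_nox,
#'                    F = attr(sim, "truth")$F)
#' @export
simulate_incubation <- function(config = sim_config(), vessel_id = "v1",
                                treatment = "control") {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, {
    t <- config$sample_times
    R_umol <- config$true_nitrification_rate / 1000  # nmol -> umol L^-1 h^-1
    F <- config$F
    nox <- config$nox0 + R_umol * t
    label <- config$r15_init * config$nox0 + R_umol * F * t
    r15 <- label / nox
    # N2O molecules produced in the vessel (pmol): atom rate / 2, times V
    n_mol <- config$true_n2o_rate / 2 * config$volume * t
    probs <- switch(config$pairing_model,
                    binomial = c(p45 = 2 * F * (1 - F), p46 = F^2),
                    single_label = c(p45 = F, p46 = 0))
    n45 <- n_mol * probs[["p45"]]
    n46 <- n_mol * probs[["p46"]]
    noisy <- function(x) {
      if (config$noise_cv == 0) x
      else x * (1 + stats::rnorm(length(x), 0, config$noise_cv))
    }
    out <- data.frame(
      vessel_id = vessel_id, treatment = treatment, time_h = t,
      nox_umol_L = noisy(nox), r15_nox = noisy(r15),
      n2o45_pmol = noisy(n45), n2o46_pmol = noisy(n46)
    )
    attr(out, "truth") <- list(
      true_nitrification_rate = config$true_nitrification_rate,
      true_n2o_rate = config$true_n2o_rate, F = F,
      pairing_model = config$pairing_model, volume = config$volume,
      probs = probs
    )
    out
  })
}

#' Simulate multi-level dose-response data with known generating curve
#'
#' Draws percent-change observations around a known polynomial response
#' curve at a set of acidification levels, with multiplicative Gaussian
#' replicate scatter: `y = curve(delta_ph) (1 + N(0, cv))`. Emulates a
#' multi-site design of several pH-reduction levels incubated in
#' triplicate.
#'
#' @param coefficients Generating polynomial coefficients for terms
#'   `delta_ph^1, delta_ph^2, ...` (zero intercept).
#' @param delta_ph_levels Acidification levels (pH units), in `[0, 1.1]`.
#' @param replicates Replicates per level (default 3).
#' @param noise_cv Multiplicative noise CV (default 0.1).
#' @param seed Integer seed, or `NULL`.
#' @param site_id Label stamped on the rows.
#' @return A data.frame of dose-response points (`site_id`, `replicate`,
#'   `delta_ph`, `percent_change`) with the generating truth in
#'   `attr(, "truth")`.
#' @export
simulate_dose_response <- function(coefficients = c(-40, -60),
                                   delta_ph_levels = c(0.1, 0.25, 0.5,
                                                       0.75, 1.05),
                                   replicates = 3, noise_cv = 0.1,
                                   seed = NULL, site_id = "site1") {
  if (any(delta_ph_levels < 0 | delta_ph_levels > 1.1)) {
    stop("delta_ph_levels must lie in [0, 1.1]", call. = FALSE)
  }
  .with_seed(seed, {
    grid <- expand.grid(replicate = seq_len(replicates),
                        delta_ph = delta_ph_levels)
    truth <- vapply(grid$delta_ph,
                    function(d) sum(coefficients * d^seq_along(coefficients)),
                    numeric(1))
    y <- if (noise_cv == 0) truth
         else truth * (1 + stats::rnorm(length(truth), 0, noise_cv))
    out <- data.frame(site_id = site_id, replicate = grid$replicate,
                      delta_ph = grid$delta_ph, percent_change = y)
    attr(out, "truth") <- list(coefficients = coefficients,
                               noise_cv = noise_cv)
    out
  })
}

#' Carbonate states of a pCO2 x pH treatment factorial
#'
#' Computes, for each cell of a factorial acidification design (CO2-adjusted
#' bubbling at target pCO2 crossed with acid/base dosing to a target pH),
#' the full carbonate state the vessel must hold — in particular the total
#' alkalinity the dosing has to set, since at fixed pCO2 the pH is
#' determined by TA alone. Deterministic: no randomness is involved.
#'
#' @inheritParams carb_constants
#' @param pco2_targets Target pCO2 levels (uatm); default `c(400, 800)`.
#' @param ph_targets Target pH levels; default `c(8.1, 7.8)`.
#' @return A data.frame with one `carbonate_state` row per factorial cell,
#'   prefixed by `pco2_target` and `ph_target` columns.
#' @examples
#' simulate_carbonate_factorial(25, 35)
#' @export
simulate_carbonate_factorial <- function(temperature = 25, salinity = 35,
                                         pco2_targets = c(400, 800),
                                         ph_targets = c(8.1, 7.8)) {
  ks <- carb_constants(temperature, salinity)
  cells <- expand.grid(pco2_target = pco2_targets, ph_target = ph_targets)
  states <- lapply(seq_len(nrow(cells)), function(i) {
    st <- state_from_ph_pco2(cells$ph_target[i], cells$pco2_target[i],
                             constants = ks)
    cbind(cells[i, , drop = FALSE], as.data.frame(st))
  })
  out <- do.call(rbind, states)
  rownames(out) <- NULL
  out
}
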