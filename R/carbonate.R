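#' Equilibrium constants for the seawater carbonate system
#'
#' Evaluates the published temperature/salinity functional forms of the
#' constants needed to speciate the carbonate system of a surface seawater
#' sample: the CO2 solubility K0 (Weiss 1974), the carbonic acid dissociation
#' constants K1 and K2 (Mehrbach et al. 1973 as refit by Dickson & Millero
#' 1987, seawater pH scale), the boric acid constant KB (Dickson 1990,
#' converted from the total to the seawater scale via the bisulfate constant
#' of Dickson 1990 and the hydrogen fluoride constant of Dickson & Riley
#' 1979), and the water ion product KW (Millero 1995, seawater scale).
#'
#' All constants are returned on the seawater pH scale (`ph_scale = "sws"`),
#' mol kg^-1 units (K0 in mol kg^-1 atm^-1). Surface pressure is assumed.
#'
#' @param temperature Water temperature (degrees C), in `[-2, 40]`.
#' @param salinity Practical salinity, in `[0, 45]`.
#' @return An object of class `carb_constants`: a list with `K0`, `K1`,
#'   `K2`, `KB`, `KW`, `ph_scale`, the environmental inputs, and a
#'   `provenance` vector naming the source of each functional form.
#' @examples
#' ks <- carb_constants(25, 35)
#' -log10(ks$K1)  # pK1 near 5.83
#' @export
carb_constants <- function(temperature, salinity) {
  if (!is.numeric(temperature) || temperature < -2 || temperature > 40) {
    stop("temperature out of supported range [-2, 40] degC", call. = FALSE)
  }
  if (!is.numeric(salinity) || salinity < 0 || salinity > 45) {
    stop("salinity out of supported range [0, 45]", call. = FALSE)
  }
  TK <- temperature + 273.15
  lnTK <- log(TK)
  S <- salinity

  # K0, Weiss (1974), mol kg^-1 atm^-1
  lnK0 <- -60.2409 + 93.4517 * (100 / TK) + 23.3585 * log(TK / 100) +
    S * (0.023517 - 0.023656 * (TK / 100) + 0.0047036 * (TK / 100)^2)

  # K1, K2: Mehrbach et al. (1973) refit by Dickson & Millero (1987), SWS
  pK1 <- 3670.7 / TK - 62.008 + 9.7944 * lnTK - 0.0118 * S + 0.000116 * S^2
  pK2 <- 1394.7 / TK + 4.777 - 0.0184 * S + 0.000118 * S^2

  # Ionic strength and total sulfate / fluoride from salinity
  IS <- 19.924 * S / (1000 - 1.005 * S)
  ST <- 0.14 / 96.062 * (S / 1.80655)      # mol kg^-1
  FT <- 0.000067 / 18.998 * (S / 1.80655)  # mol kg^-1

  # KS, Dickson (1990), free scale
  lnKS <- -4276.1 / TK + 141.328 - 23.093 * lnTK +
    (-13856 / TK + 324.57 - 47.986 * lnTK) * sqrt(IS) +
    (35474 / TK - 771.54 + 114.723 * lnTK) * IS -
    2698 / TK * IS^1.5 + 1776 / TK * IS^2 + log(1 - 0.001005 * S)
  KS <- exp(lnKS)

  # KF, Dickson & Riley (1979), free scale
  lnKF <- 1590.2 / TK - 12.641 + 1.525 * sqrt(IS) + log(1 - 0.001005 * S)
  KF <- exp(lnKF)

  # total -> seawater scale conversion factor
  tot_to_sws <- (1 + ST / KS + FT / KF) / (1 + ST / KS)

  # KB, Dickson (1990), total scale; convert to SWS
  lnKB <- (-8966.90 - 2890.53 * sqrt(S) - 77.942 * S + 1.728 * S^1.5 -
             0.0996 * S^2) / TK +
    148.0248 + 137.1942 * sqrt(S) + 1.62142 * S -
    (24.4344 + 25.085 * sqrt(S) + 0.2474 * S) * lnTK +
    0.053105 * sqrt(S) * TK
  KB <- exp(lnKB) * tot_to_sws

  # KW, Millero (1995), seawater scale
  lnKW <- 148.9802 - 13847.26 / TK - 23.6521 * lnTK +
    (-5.977 + 118.67 / TK + 1.0495 * lnTK) * sqrt(S) - 0.01615 * S

  structure(
    list(
      K0 = exp(lnK0), K1 = 10^(-pK1), K2 = 10^(-pK2),
      KB = KB, KW = exp(lnKW),
      temperature = temperature, salinity = salinity,
      ph_scale = "sws",
      provenance = c(
        K0 = "Weiss 1974", K1 = "Mehrbach 1973 refit Dickson & Millero 1987",
        K2 = "Mehrbach 1973 refit Dickson & Millero 1987",
        KB = "Dickson 1990 (total->SWS via Dickson 1990 KS, Dickson & Riley 1979 KF)",
        KW = "Millero 1995", boron = "Uppstrom 1974"
      )
    ),
    class = "carb_constants"
  )
}

#' @export
print.carb_constants <- function(x, ...) {
  cat(sprintf(
    "<carb_constants> T = %g degC, S = %g, scale = %s\n  pK1 = %.4f  pK2 = %.4f  pKB = %.4f  pKW = %.4f  K0 = %.5f\n",
    x$temperature, x$salinity, x$ph_scale, -log10(x$K1), -log10(x$K2),
    -log10(x$KB), -log10(x$KW), x$K0))
  invisible(x)
}

#' Total boron from salinity
#'
#' Uppstrom (1974) boron-to-chlorinity ratio: total boron is linear in
#' salinity and zero in fresh water.
#'
#' @param salinity Practical salinity, in `[0, 45]`.
#' @return Total boron (umol kg^-1).
#' @examples
#' total_boron(35)  # about 416 umol kg^-1
#' @export
total_boron <- function(salinity) {
  if (any(salinity < 0 | salinity > 45)) {
    stop("salinity out of supported range [0, 45]", call. = FALSE)
  }
  0.0004157 * salinity / 35 * 1e6
}

#' Convert pH from the NBS to the seawater scale
#'
#' The glass-electrode (NBS) and seawater pH scales differ by the activity
#' factor fH of the hydrogen ion in seawater media; this applies the
#' empirical fH of Takahashi et al. (1982): `pH_sws = pH_nbs + log10(fH)`.
#' The solver itself treats input pH as being on its working (seawater)
#' scale; apply this conversion explicitly when the measurement is NBS.
#'
#' @param ph_nbs pH on the NBS scale.
#' @inheritParams carb_constants
#' @return pH on the seawater scale.
#' @export
ph_nbs_to_sws <- function(ph_nbs, temperature, salinity) {
  TK <- temperature + 273.15
  fH <- 1.2948 - 0.002036 * TK + (0.0004607 - 0.000001475 * TK) * salinity^2
  ph_nbs + log10(fH)
}

# Species (umol kg^-1) from [H+] (mol kg^-1) and DIC (umol kg^-1).
.species_from_h_dic <- function(h, dic, ks) {
  denom <- h^2 + ks$K1 * h + ks$K1 * ks$K2
  co2_star <- dic * h^2 / denom
  hco3 <- dic * ks$K1 * h / denom
  co3 <- dic * ks$K1 * ks$K2 / denom
  tb <- total_boron(ks$salinity)
  boh4 <- tb * ks$KB / (ks$KB + h)
  oh <- ks$KW / h * 1e6
  h_umol <- h * 1e6
  list(co2_star = co2_star, hco3 = hco3, co3 = co3, boh4 = boh4,
       oh = oh, h = h_umol,
       ta = hco3 + 2 * co3 + boh4 + oh - h_umol)
}

.carbonate_state <- function(ph, dic, sp, ks) {
  data.frame(
    ph = ph, dic = dic, ta = sp$ta,
    pco2 = sp$co2_star * 1e-6 / ks$K0 * 1e6,  # umol/kg -> mol/kg; atm -> uatm
    co2_star = sp$co2_star, hco3 = sp$hco3, co3 = sp$co3,
    boh4 = sp$boh4, oh = sp$oh, h = sp$h,
    temperature = ks$temperature, salinity = ks$salinity
  )
}

#' Carbonate speciation from pH and DIC
#'
#' Closed-form speciation of a surface seawater sample from measured pH and
#' dissolved inorganic carbon, the calculation the incubation workflow runs
#' on every water sample: ionization fractions of CO2*/HCO3-/CO3^2- at
#' `[H+] = 10^-pH`, borate from total boron, and the derived total
#' alkalinity (carbonate + borate + water terms) and pCO2 (`= CO2*/K0`).
#'
#' Concentrations are per kilogram of solution (umol kg^-1). For incubation
#' bookkeeping in volumetric units the approximation 1 L = 1 kg is adequate
#' at these salinities and is left to the caller.
#'
#' @param ph pH on the solver's working (seawater) scale, in `[2, 12]`.
#' @param dic Dissolved inorganic carbon (umol kg^-1), >= 0.
#' @inheritParams carb_constants
#' @param constants Optional precomputed [carb_constants()].
#' @return A one-row data.frame (class `carbonate_state`) with columns `ph`,
#'   `dic`, `ta`, `pco2` (uatm) and the species `co2_star`, `hco3`, `co3`,
#'   `boh4`, `oh`, `h` (umol kg^-1), plus `temperature` and `salinity`.
#' @examples
#' speciate_from_ph_dic(8.1, 2000, temperature = 25, salinity = 35)
#' @export
speciate_from_ph_dic <- function(ph, dic, temperature, salinity,
                                 constants = NULL) {
  if (ph < 2 || ph > 12) stop("ph out of range [2, 12]", call. = FALSE)
  if (dic < 0) stop("dic must be non-negative", call. = FALSE)
  ks <- constants %||% carb_constants(temperature, salinity)
  sp <- .species_from_h_dic(10^(-ph), dic, ks)
  out <- .carbonate_state(ph, dic, sp, ks)
  class(out) <- c("carbonate_state", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Solve pH from total alkalinity and DIC
#'
#' Inverts the alkalinity expression for `[H+]`: finds the root of
#' `TA(pH, DIC) - TA` by safeguarded bracketing on pH in `[2, 12]`
#' ([stats::uniroot()]), to an absolute tolerance of 1e-10 pH units. If the
#' bracket contains no sign change the input pair is reported as infeasible
#' rather than extrapolated.
#'
#' @param ta Total alkalinity (umol kg^-1).
#' @param dic Dissolved inorganic carbon (umol kg^-1).
#' @inheritParams speciate_from_ph_dic
#' @return A `carbonate_state` row, as [speciate_from_ph_dic()].
#' @examples
#' st <- speciate_from_ph_dic(8.1, 2000, 25, 35)
#' solve_ph_from_ta_dic(st$ta, 2000, 25, 35)$ph  # 8.1
#' @export
solve_ph_from_ta_dic <- function(ta, dic, temperature, salinity,
                                 constants = NULL) {
  ks <- constants %||% carb_constants(temperature, salinity)
  f <- function(ph) .species_from_h_dic(10^(-ph), dic, ks)$ta - ta
  lo <- f(2); hi <- f(12)
  if (is.na(lo) || is.na(hi) || lo * hi > 0) {
    stop("no pH in [2, 12] matches this (TA, DIC) pair", call. = FALSE)
  }
  root <- stats::uniroot(f, c(2, 12), tol = 1e-10)
  speciate_from_ph_dic(root$root, dic, constants = ks)
}

# TA implied by (pH, pCO2): CO2* is fixed by solubility, carbonate species
# follow from [H+].
.species_from_h_pco2 <- function(h, pco2, ks) {
  co2_star <- ks$K0 * pco2 * 1e-6 * 1e6  # uatm -> atm; mol/kg -> umol/kg
  hco3 <- ks$K1 * co2_star / h
  co3 <- ks$K2 * hco3 / h
  tb <- total_boron(ks$salinity)
  boh4 <- tb * ks$KB / (ks$KB + h)
  oh <- ks$KW / h * 1e6
  h_umol <- h * 1e6
  list(co2_star = co2_star, hco3 = hco3, co3 = co3, boh4 = boh4,
       oh = oh, h = h_umol,
       ta = hco3 + 2 * co3 + boh4 + oh - h_umol,
       dic = co2_star + hco3 + co3)
}

#' Carbonate state from pH and pCO2
#'
#' Closed-form state at a prescribed pH and CO2 partial pressure: CO2* is
#' fixed by solubility, the remaining species by `[H+]`. This is the
#' treatment-design direction used to derive the alkalinity a bubbled,
#' acid/base-dosed vessel must hold to sit at a target (pCO2, pH) cell.
#'
#' @param ph pH on the working scale, in `[2, 12]`.
#' @param pco2 CO2 partial pressure (uatm), > 0.
#' @inheritParams speciate_from_ph_dic
#' @return A `carbonate_state` row.
#' @export
state_from_ph_pco2 <- function(ph, pco2, temperature, salinity,
                               constants = NULL) {
  if (ph < 2 || ph > 12) stop("ph out of range [2, 12]", call. = FALSE)
  if (pco2 <= 0) stop("pco2 must be positive", call. = FALSE)
  ks <- constants %||% carb_constants(temperature, salinity)
  sp <- .species_from_h_pco2(10^(-ph), pco2, ks)
  out <- .carbonate_state(ph, sp$dic, sp, ks)
  class(out) <- c("carbonate_state", "data.frame")
  out
}

#' Solve the carbonate system from total alkalinity and pCO2
#'
#' Finds the pH (and hence DIC) at which a water parcel of the given total
#' alkalinity is in equilibrium with the given CO2 partial pressure — the
#' state a continuously bubbled vessel relaxes to. Same bracketing and
#' tolerance contract as [solve_ph_from_ta_dic()].
#'
#' @param ta Total alkalinity (umol kg^-1), > 0.
#' @param pco2 CO2 partial pressure (uatm), > 0.
#' @inheritParams speciate_from_ph_dic
#' @return A `carbonate_state` row.
#' @examples
#' solve_from_ta_pco2(2300, 400, 25, 35)$ph
#' @export
solve_from_ta_pco2 <- function(ta, pco2, temperature, salinity,
                               constants = NULL) {
  if (ta <= 0 || pco2 <= 0) stop("ta and pco2 must be positive", call. = FALSE)
  ks <- constants %||% carb_constants(temperature, salinity)
  f <- function(ph) .species_from_h_pco2(10^(-ph), pco2, ks)$ta - ta
  lo <- f(2); hi <- f(12)
  if (is.na(lo) || is.na(hi) || lo * hi > 0) {
    stop("no pH in [2, 12] matches this (TA, pCO2) pair", call. = FALSE)
  }
  root <- stats::uniroot(f, c(2, 12), tol = 1e-10)
  state_from_ph_pco2(root$root, pco2, constants = ks)
}
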