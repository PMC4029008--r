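#' IP3R gating dissociation constants
#'
#' Equilibrium dissociation constants for the steady-state open-probability
#' model of the IP3 receptor. The shipped defaults are repo defaults with
#' DeYoung-Keizer-style magnitudes (uM); they are placeholders for exploring
#' the model shape and should be replaced with measured values for scientific
#' use.
#'
#' @param K_CaI Dissociation constant for Ca2+-dependent channel inhibition (uM).
#' @param K_IP3_1,K_IP3_2 IP3 dissociation constants (uM).
#' @param K_CaA Dissociation constant for Ca2+-dependent activation (uM).
#' @return An object of class `gating_constants`.
#' @export
gating_constants <- function(K_CaI = 1.049, K_IP3_1 = 0.13,
                             K_IP3_2 = 0.9434, K_CaA = 0.08234) {
  vals <- c(K_CaI = K_CaI, K_IP3_1 = K_IP3_1, K_IP3_2 = K_IP3_2, K_CaA = K_CaA)
  if (any(vals <= 0)) abort("All dissociation constants must be > 0.")
  structure(as.list(vals), class = "gating_constants")
}

#' Steady-state IP3R open probability
#'
#' Probability that a tetrameric IP3R conducts, as the cube of a per-monomer
#' occupancy factor combining IP3 binding, Ca2+ activation and Ca2+
#' inhibition:
#' `p_O = [ ca*ip3*K_CaI / ((ca*ip3 + ip3*K_CaI + K_IP3_1*K_CaI + ca*K_IP3_2) * (ca + K_CaA)) ]^3`.
#' At fixed saturating IP3 the profile is bell-shaped in Ca2+: low
#' concentrations activate the channel, high concentrations inhibit it.
#'
#' @param ca Cytosolic free Ca2+ (uM), >= 0 (vectorized).
#' @param ip3 Cytosolic IP3 (uM), >= 0 (vectorized).
#' @param k A [gating_constants()] object.
#' @return Open probability in `[0, 1]`.
#' @examples
#' open_probability(0.3, 0.5)
#' @export
open_probability <- function(ca, ip3, k = gating_constants()) {
  if (any(ca < 0) || any(ip3 < 0)) abort("`ca` and `ip3` must be >= 0.")
  num <- ca * ip3 * k$K_CaI
  den <- (ca * ip3 + ip3 * k$K_CaI + k$K_IP3_1 * k$K_CaI + ca * k$K_IP3_2) *
    (ca + k$K_CaA)
  (num / den)^3
}

#' Flux parameters for the extended release balance
#'
#' Constants and state for the flux-based generalization of Gamma: channel
#' release and leak out of the ER, SERCA-type re-uptake, and buffer binding.
#' Defaults are repo defaults with DeYoung-Keizer-style magnitudes and are
#' not measured values.
#'
#' @param C_ER_C ER/cytosol volume-ratio factor (dimensionless).
#' @param F_MO Maximum outward IP3R flux coefficient (per s).
#' @param F_L Leak flux coefficient (per s).
#' @param F_U Maximum ER uptake rate (uM/s).
#' @param A Uptake-activation constant (uM).
#' @param K_B Buffer binding constant (1/(uM s)).
#' @param ca_ER,ca_C Free ER and cytosolic Ca2+ (uM).
#' @param B_C Free buffer concentration (uM).
#' @return An object of class `flux_params`.
#' @export
flux_params <- function(C_ER_C = 0.185, F_MO = 6, F_L = 0.11,
                        F_U = 0.9, A = 0.1, K_B = 5,
                        ca_ER = 400, ca_C = 0.2, B_C = 10) {
  if (any(c(C_ER_C, F_MO, F_L, F_U, A, K_B) < 0)) {
    abort("Rate constants must be >= 0.")
  }
  if (any(c(ca_ER, ca_C, B_C) < 0)) abort("Concentrations must be >= 0.")
  structure(list(C_ER_C = C_ER_C, F_MO = F_MO, F_L = F_L, F_U = F_U,
                 A = A, K_B = K_B, ca_ER = ca_ER, ca_C = ca_C, B_C = B_C),
            class = "flux_params")
}

#' Release, re-uptake and buffering flux terms
#'
#' The three flux contributions to the extended Gamma:
#' `Phi1 = C_ER_C * (F_MO * p_O + F_L) * (ca_ER - ca_C)` (store release and
#' leak down the ER gradient), `Phi2 = F_U * ca_C^2 / (ca_C^2 + A^2)`
#' (Hill-type re-uptake) and `Phi3 = K_B * ca_C * B_C` (buffer capture).
#'
#' @param f A [flux_params()] object.
#' @param p_open IP3R open probability, e.g. from [open_probability()].
#' @return A tibble with columns `phi1`, `phi2`, `phi3` (uM/s).
#' @export
phi_terms <- function(f, p_open) {
  stopifnot(inherits(f, "flux_params"))
  if (any(p_open < 0 | p_open > 1)) abort("`p_open` must lie in [0, 1].")
  tibble::tibble(
    phi1 = f$C_ER_C * (f$F_MO * p_open + f$F_L) * (f$ca_ER - f$ca_C),
    phi2 = if (f$ca_C == 0 && f$A == 0) 0 else f$F_U * f$ca_C^2 / (f$ca_C^2 + f$A^2),
    phi3 = f$K_B * f$ca_C * f$B_C
  )
}

#' Flux-based extended Gamma
#'
#' Generalizes the release-strength parameter to a net flux balance:
#' `Gamma = (Phi1 - Phi2 - Phi3) / (ca_threshold - ca_basal)`. The
#' denominator is taken as the threshold excess (the kinetic weighting left
#' unspecified in the source formulation is assumed to cancel). A negative
#' value means re-uptake and buffering dominate release, in which case waves
#' cannot initiate and downstream classification returns failure rather than
#' an error.
#'
#' @param f A [flux_params()] object.
#' @param p_open IP3R open probability.
#' @param ca_threshold,ca_basal Threshold and basal Ca2+ (uM),
#'   `ca_threshold > ca_basal`.
#' @return Extended Gamma (dimensionless net flux per threshold excess, 1/s
#'   scale absorbed in the flux constants; may be negative).
#' @export
extended_gamma <- function(f, p_open, ca_threshold, ca_basal) {
  if (any(ca_threshold <= ca_basal)) {
    abort("`ca_threshold` must exceed `ca_basal`.")
  }
  phi <- phi_terms(f, p_open)
  (phi$phi1 - phi$phi2 - phi$phi3) / (ca_threshold - ca_basal)
}

#' Bell-shape summary of the open-probability curve
#'
#' Grid scan of [open_probability()] in Ca2+ at fixed IP3, returning the
#' maximizing Ca2+, the maximum p_O and the number of interior local maxima
#' (1 for the expected bell shape).
#'
#' @param ip3 IP3 concentration (uM).
#' @param k A [gating_constants()] object.
#' @param ca_range Range of Ca2+ scanned (uM).
#' @param n Grid size.
#' @return A tibble with `ca_max`, `p_max`, `n_interior_maxima`.
#' @export
open_probability_profile <- function(ip3, k = gating_constants(),
                                     ca_range = c(1e-3, 100), n = 2000) {
  ca <- exp(seq(log(ca_range[[1]]), log(ca_range[[2]]), length.out = n))
  p <- open_probability(ca, ip3, k)
  interior <- which(diff(sign(diff(p))) == -2) + 1L
  tibble::tibble(
    ca_max = ca[[which.max(p)]],
    p_max = max(p),
    n_interior_maxima = length(interior)
  )
}
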