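#' Dimensionless release strength Gamma
#'
#' Gamma is the ratio of the calcium concentration liberated by one release
#' event, `sigma/d^3`, to the threshold excess `[Ca]_T - [Ca]_b` that a site
#' must see before it fires. It controls how easily a wave ignites and the
#' velocity it reaches.
#'
#' @param sigma_conc Released concentration sigma/d^3 (uM).
#' @param ca_threshold Firing threshold concentration (uM).
#' @param ca_basal Basal (resting) cytosolic concentration (uM).
#' @return Dimensionless Gamma (vectorized).
#' @examples
#' compute_gamma(5, 0.6, 0.1)  # 10
#' @export
compute_gamma <- function(sigma_conc, ca_threshold, ca_basal) {
  if (any(sigma_conc < 0)) abort("`sigma_conc` must be >= 0.")
  if (any(ca_basal < 0)) abort("`ca_basal` must be >= 0.")
  if (any(ca_threshold <= ca_basal)) {
    abort("`ca_threshold` must exceed `ca_basal`.")
  }
  sigma_conc / (ca_threshold - ca_basal)
}

#' Dimensionless propagation-mode parameter beta
#'
#' beta decides whether a front is saltatory (site-to-site hops limited by
#' diffusion, beta well below 1) or continuous (release-kinetics limited,
#' beta >> 1). Two conventions are available because the combination
#' `D*tau/d^2` reproduces every published worked value (e.g. D = 190 um^2/s,
#' tau = 0.04 s, d = 2 um gives beta = 1.9), whereas the once-printed literal
#' form `(D/tau)/d^2` does not; the latter is kept for comparison.
#'
#' @param D Calcium diffusion coefficient (um^2/s).
#' @param tau Release (channel open) duration (s).
#' @param d Inter-site spacing (um).
#' @param convention `"worked_example"` (default, `D*tau/d^2`) or
#'   `"as_printed"` (`(D/tau)/d^2`).
#' @return Dimensionless beta (vectorized).
#' @examples
#' compute_beta(190, 0.04, 2)     # 1.9  (continuous)
#' compute_beta(15, 0.04, 2)      # 0.15 (saltatory)
#' compute_beta(190, 0.04, 0.02)  # 19000 (intracluster scale)
#' @export
compute_beta <- function(D, tau, d,
                         convention = c("worked_example", "as_printed")) {
  convention <- match.arg(convention)
  if (any(D <= 0) || any(tau <= 0) || any(d <= 0)) {
    abort("`D`, `tau` and `d` must all be positive.")
  }
  switch(convention,
    worked_example = D * tau / d^2,
    as_printed     = (D / tau) / d^2
  )
}

#' Saltatory wave velocity
#'
#' In the saltatory regime the front hops from site to site and travels at a
#' rate proportional to the diffusion coefficient, `v = (D/d) * geometry_factor`.
#' The unspecified inverse-function/Gamma product of the velocity law is
#' collapsed into a single configurable `geometry_factor` (default 1, the value
#' implied by the worked example v ~ D/d ~ 7.5 um/s at D = 15, d = 2).
#'
#' @param D Diffusion coefficient (um^2/s), >= 0.
#' @param d Inter-site spacing (um), > 0.
#' @param geometry_factor Dimensionless multiplier (default 1).
#' @return Velocity in um/s (vectorized).
#' @examples
#' saltatory_velocity(15, 2)  # 7.5
#' @export
saltatory_velocity <- function(D, d, geometry_factor = 1) {
  if (any(D < 0)) abort("`D` must be >= 0.")
  if (any(d <= 0)) abort("`d` must be > 0.")
  (D / d) * geometry_factor
}

#' Continuous wave velocity (Luther form)
#'
#' In the continuous regime velocity is proportional to the square root of the
#' diffusion coefficient, `v = gamma_factor * sqrt(D/tau)`; with sufficiently
#' large Gamma the prefactor is alpha = sqrt(Gamma) (Luther equation). The
#' default `gamma_factor = 1` matches the worked example
#' v ~ sqrt(D/tau) ~ 69 um/s at D = 190, tau = 0.04.
#'
#' @param D Diffusion coefficient (um^2/s), >= 0.
#' @param tau Release duration (s), > 0.
#' @param gamma_factor Dimensionless prefactor (default 1; use sqrt(Gamma) for
#'   the Luther asymptote).
#' @return Velocity in um/s (vectorized).
#' @examples
#' continuous_velocity(190, 0.04)  # 68.9
#' @export
continuous_velocity <- function(D, tau, gamma_factor = 1) {
  if (any(D < 0)) abort("`D` must be >= 0.")
  if (any(tau <= 0)) abort("`tau` must be > 0.")
  gamma_factor * sqrt(D / tau)
}

#' Invert a velocity law for the diffusion coefficient
#'
#' Recovers D from an observed front velocity: `D_S = v*d*g/Gamma` for
#' saltatory fronts and `D_C = tau*(v*f/Gamma)^2` for continuous fronts, with
#' the unspecified functions g and f taken as `geometry_factor`.
#'
#' @param v Front velocity (um/s), >= 0.
#' @param mode `"saltatory"` or `"continuous"`.
#' @param d Inter-site spacing (um); used for saltatory.
#' @param tau Release duration (s); used for continuous.
#' @param gamma Dimensionless Gamma, > 0.
#' @param geometry_factor Dimensionless g or f (default 1).
#' @return Diffusion coefficient in um^2/s.
#' @examples
#' diffusion_from_velocity(7.5, "saltatory", d = 2, gamma = 1)        # 15
#' diffusion_from_velocity(69, "continuous", tau = 0.04, gamma = 1)   # ~190
#' @export
diffusion_from_velocity <- function(v, mode = c("saltatory", "continuous"),
                                    d = NULL, tau = NULL, gamma = 1,
                                    geometry_factor = 1) {
  mode <- match.arg(mode)
  if (any(v < 0)) abort("`v` must be >= 0.")
  if (any(gamma == 0)) abort("`gamma` must be nonzero.")
  if (mode == "saltatory") {
    if (is.null(d)) abort("`d` is required for saltatory mode.")
    v * d * geometry_factor / gamma
  } else {
    if (is.null(tau)) abort("`tau` is required for continuous mode.")
    tau * (v * geometry_factor / gamma)^2
  }
}

#' Invert a velocity law for Gamma
#'
#' Register-index form of the wave laws: `Gamma_S = tau*v*g/(beta*d)` and
#' `Gamma_C = v*f/(sqrt(beta)*d)`. Under the worked-example beta convention
#' Gamma_S recovers the Gamma used to generate v exactly; Gamma_C recovers
#' sqrt(Gamma) under the as-printed convention (a residual convention mismatch
#' inherited from the source laws, kept as-is rather than silently reconciled).
#'
#' @param v Front velocity (um/s), >= 0.
#' @param mode `"saltatory"` or `"continuous"`.
#' @param beta Dimensionless beta, > 0.
#' @param d Inter-site spacing (um).
#' @param tau Release duration (s); used for saltatory.
#' @param geometry_factor Dimensionless g or f (default 1).
#' @return Dimensionless Gamma index value.
#' @export
gamma_from_velocity <- function(v, mode = c("saltatory", "continuous"),
                                beta, d, tau = NULL, geometry_factor = 1) {
  mode <- match.arg(mode)
  if (any(v < 0)) abort("`v` must be >= 0.")
  if (any(beta <= 0)) abort("`beta` must be > 0.")
  if (any(d <= 0)) abort("`d` must be > 0.")
  if (mode == "saltatory") {
    if (is.null(tau)) abort("`tau` is required for saltatory mode.")
    tau * v * geometry_factor / (beta * d)
  } else {
    v * geometry_factor / (sqrt(beta) * d)
  }
}

#' Classify propagation regime from Gamma, beta and geometry
#'
#' Conduction fails for small D when the mode would otherwise be saltatory
#' (default D < 10 um^2/s), for large spacing (default d > 3 um), and for
#' Gamma outside a configurable band (very small Gamma cannot ignite
#' neighbours; very large Gamma is outside the model's validity). Otherwise
#' the front is continuous for beta >= `beta_hi` (default 1), saltatory for
#' beta <= `beta_lo` (default 0.5), and mixed in between. The model velocity
#' uses the matching law; mixed fronts get no single model velocity.
#'
#' @param gamma,beta Dimensionless wave parameters (vectorized).
#' @param D Diffusion coefficient (um^2/s).
#' @param d Inter-site spacing (um).
#' @param beta_lo,beta_hi Regime thresholds on beta (defaults 0.5 and 1).
#' @param gamma_band Length-2 numeric, admissible (Gamma_min, Gamma_max)
#'   (default `c(0.1, 100)`).
#' @param D_fail Saltatory conduction-failure threshold on D (default 10).
#' @param d_fail Spacing failure threshold (default 3 um).
#' @param tau Release duration (s), needed for the continuous velocity.
#' @param geometry_factor Dimensionless prefactor passed to the velocity laws.
#' @return A tibble with columns `gamma`, `beta`, `regime` (factor levels
#'   saltatory/continuous/mixed/failure), `model_velocity` (um/s, NA when the
#'   regime defines none) and `geometry_factor`.
#' @examples
#' classify_regime(gamma = 10, beta = 1.9, D = 190, d = 2, tau = 0.04)
#' @export
classify_regime <- function(gamma, beta, D, d,
                            beta_lo = 0.5, beta_hi = 1.0,
                            gamma_band = c(0.1, 100),
                            D_fail = 10, d_fail = 3,
                            tau = NULL, geometry_factor = 1) {
  n <- max(length(gamma), length(beta), length(D), length(d))
  gamma <- rep_len(gamma, n); beta <- rep_len(beta, n)
  D <- rep_len(D, n); d <- rep_len(d, n)
  would_be_saltatory <- beta <= beta_lo
  fail <- (D < D_fail & would_be_saltatory) | d > d_fail |
    gamma < gamma_band[[1]] | gamma > gamma_band[[2]]
  regime <- dplyr::case_when(
    fail ~ "failure",
    beta >= beta_hi ~ "continuous",
    beta <= beta_lo ~ "saltatory",
    TRUE ~ "mixed"
  )
  v <- rep(NA_real_, n)
  salt <- regime == "saltatory"
  cont <- regime == "continuous"
  if (any(salt)) v[salt] <- saltatory_velocity(D[salt], d[salt], geometry_factor)
  if (any(cont)) {
    if (is.null(tau)) abort("`tau` is required to compute continuous velocities.")
    tau_v <- rep_len(tau, n)
    v[cont] <- continuous_velocity(D[cont], tau_v[cont], geometry_factor)
  }
  tibble::tibble(
    gamma = gamma, beta = beta,
    regime = factor(regime, levels = c("saltatory", "continuous", "mixed", "failure")),
    model_velocity = v,
    geometry_factor = geometry_factor
  )
}

#' Classify a table of wave parameter sets
#'
#' Data-frame-first wrapper around [compute_gamma()], [compute_beta()] and
#' [classify_regime()]: takes one parameter set per row and appends the
#' dimensionless parameters, the regime label and the model velocity.
#'
#' @param data A data frame with columns `D`, `tau`, `d` and either `gamma` or
#'   (`sigma_conc`, `ca_threshold`, `ca_basal`).
#' @param convention beta convention, see [compute_beta()].
#' @param ... Passed to [classify_regime()] (thresholds, geometry factor).
#' @return The input as a tibble with columns `gamma`, `beta`, `regime` and
#'   `model_velocity` appended.
#' @examples
#' tibble::tibble(D = c(190, 15), tau = 0.04, d = 2, gamma = 10) |>
#'   classify_waves()
#' @export
classify_waves <- function(data, convention = "worked_example", ...) {
  data <- tibble::as_tibble(data)
  need <- c("D", "tau", "d")
  if (!all(need %in% names(data))) {
    abort("`data` must contain columns D, tau and d.")
  }
  if (!"gamma" %in% names(data)) {
    if (!all(c("sigma_conc", "ca_threshold", "ca_basal") %in% names(data))) {
      abort("`data` needs a `gamma` column or sigma_conc/ca_threshold/ca_basal.")
    }
    data$gamma <- compute_gamma(data$sigma_conc, data$ca_threshold, data$ca_basal)
  }
  beta <- compute_beta(data$D, data$tau, data$d, convention = convention)
  cls <- classify_regime(data$gamma, beta, data$D, data$d, tau = data$tau, ...)
  data$beta <- cls$beta
  data$regime <- cls$regime
  data$model_velocity <- cls$model_velocity
  data
}
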