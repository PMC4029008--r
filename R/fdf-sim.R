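#' Fire-diffuse-fire model parameters
#'
#' Physical parameters of the one-dimensional fire-diffuse-fire model: point
#' release sites on a line fire a fixed quantity of calcium for a duration
#' `tau` once the local concentration first reaches `ca_threshold`, and the
#' released calcium couples sites by passive diffusion. Sites fire exactly
#' once (deterministic refractoriness); re-uptake and extrusion are not part
#' of this evolution equation.
#'
#' @param D Diffusion coefficient (um^2/s), >= 0.
#' @param d Mean inter-site spacing (um), > 0.
#' @param sigma_conc Released concentration sigma/d^3 (uM), >= 0.
#' @param tau Release duration (s), > 0.
#' @param ca_threshold Firing threshold (uM), > `ca_basal`.
#' @param ca_basal Basal concentration (uM), >= 0.
#' @param site_positions Optional strictly increasing site coordinates (um);
#'   defaults to `n_sites` regularly spaced sites at spacing `d`.
#' @param n_sites Number of sites when `site_positions` is NULL (default 20).
#' @return An object of class `fdf_params`.
#' @examples
#' p <- fdf_params(D = 190, d = 2, sigma_conc = 5, tau = 0.04)
#' @export
fdf_params <- function(D, d, sigma_conc, tau,
                       ca_threshold = 0.6, ca_basal = 0.1,
                       site_positions = NULL, n_sites = 20) {
  if (D < 0) abort("`D` must be >= 0.")
  if (d <= 0) abort("`d` must be > 0.")
  if (sigma_conc < 0) abort("`sigma_conc` must be >= 0.")
  if (tau <= 0) abort("`tau` must be > 0.")
  if (ca_basal < 0) abort("`ca_basal` must be >= 0.")
  if (ca_threshold <= ca_basal) abort("`ca_threshold` must exceed `ca_basal`.")
  if (is.null(site_positions)) {
    site_positions <- seq(0, by = d, length.out = n_sites)
  }
  if (length(site_positions) < 1 || is.unsorted(site_positions, strictly = TRUE)) {
    abort("`site_positions` must be strictly increasing.")
  }
  structure(
    list(D = D, d = d, sigma_conc = sigma_conc, tau = tau,
         ca_threshold = ca_threshold, ca_basal = ca_basal,
         site_positions = as.numeric(site_positions)),
    class = "fdf_params"
  )
}

#' @export
print.fdf_params <- function(x, ...) {
  cat("<fdf_params> D =", x$D, "um^2/s, d =", x$d, "um, sigma/d^3 =",
      x$sigma_conc, "uM, tau =", x$tau, "s\n")
  cat("  threshold", x$ca_threshold, "uM over basal", x$ca_basal, "uM;",
      length(x$site_positions), "sites\n")
  invisible(x)
}

#' Discretization grid for the fire-diffuse-fire simulation
#'
#' Default resolution is `dx = d/20` (resolving inter-site gradients) and
#' `dt = 0.4 * dx^2 / (2 D)`, safely inside the explicit-scheme stability
#' bound `dt <= dx^2 / (2 D)`. Boundaries are reflecting (zero flux) by
#' default so that total calcium is conserved; absorbing boundaries clamp the
#' end nodes to basal.
#'
#' @param params An [fdf_params()] object.
#' @param dx Spatial step (um).
#' @param dt Time step (s); default 0.4 of the stability limit.
#' @param length Domain length (um); default spans the sites plus a margin.
#' @param t_max Maximum simulated time (s); default estimated from the wave
#'   velocity laws with a generous margin.
#' @param boundary `"reflecting"` or `"absorbing"`.
#' @return An object of class `sim_grid`.
#' @export
sim_grid <- function(params, dx = params$d / 20, dt = NULL,
                     length = NULL, t_max = NULL,
                     boundary = c("reflecting", "absorbing")) {
  boundary <- match.arg(boundary)
  if (dx <= 0) abort("`dx` must be > 0.")
  if (is.null(dt)) {
    dt <- if (params$D > 0) 0.4 * dx^2 / (2 * params$D) else params$tau / 20
  }
  if (dt <= 0) abort("`dt` must be > 0.")
  if (params$D > 0 && dt > dx^2 / (2 * params$D)) {
    abort(sprintf(
      "Unstable time step: dt = %.3g exceeds the stability limit dx^2/(2D) = %.3g.",
      dt, dx^2 / (2 * params$D)))
  }
  span <- diff(range(params$site_positions))
  if (is.null(length)) length <- span + 4 * params$d
  if (length < span) abort("`length` must cover the release sites.")
  if (is.null(t_max)) {
    gam <- params$sigma_conc / (params$ca_threshold - params$ca_basal)
    if (params$D > 0) {
      v_salt <- params$D / params$d
      v_cont <- sqrt(max(gam, 1) * params$D / params$tau)
      t_max <- 8 * length / min(v_salt, v_cont) + 10 * params$tau
    } else {
      t_max <- 5 * params$tau
    }
  }
  structure(
    list(dx = dx, dt = dt, length = length, t_max = t_max, boundary = boundary),
    class = "sim_grid"
  )
}

#' Simulate the fire-diffuse-fire model
#'
#' Explicit finite-difference integration of
#' `dc/dt = D d2c/dx2 + sum_i (sigma/(d^2 tau)) delta(x - x_i) H(t - t_i) H(t_i + tau - t)`
#' on a 1-D domain. The trigger site fires at t = 0; every other site fires
#' once, at the first time the concentration at its nearest grid node reaches
#' `ca_threshold`. Each release deposits exactly `sigma/d^2` (concentration x
#' length) spread over `round(tau/dt)` steps at the nearest node, so with
#' reflecting boundaries total calcium is conserved to floating point.
#'
#' @param params An [fdf_params()] object.
#' @param grid A [sim_grid()]; defaults to `sim_grid(params)`.
#' @param trigger Index of the site triggered at t = 0 (default 1, the
#'   leftmost site). Use `trigger = NA` for an unperturbed run (nothing fires).
#' @param n_snapshots Number of concentration snapshots to retain (default 40).
#' @param propagation_fraction Fraction of sites that must fire for
#'   `propagated = TRUE` (default 0.9).
#' @return An object of class `fdf_sim` with elements `firings` (tibble:
#'   site, position_um, t_fire_s), `snapshots` (tibble: t_s, x_um, ca_uM),
#'   `estimated_velocity` (um/s or NA), `propagated`, `mass_balance` and the
#'   inputs. Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' p <- fdf_params(D = 30, d = 2, sigma_conc = 5, tau = 0.04, n_sites = 8)
#' sim <- simulate_fdf(p)
#' glance(sim)
#' @export
simulate_fdf <- function(params, grid = sim_grid(params), trigger = 1,
                         n_snapshots = 40, propagation_fraction = 0.9) {
  stopifnot(inherits(params, "fdf_params"), inherits(grid, "sim_grid"))
  sites <- params$site_positions
  n_sites <- length(sites)
  if (!is.na(trigger) && (trigger < 1 || trigger > n_sites)) {
    abort("`trigger` must be a valid site index or NA.")
  }
  dx <- grid$dx; dt <- grid$dt
  if (params$D > 0 && dt > dx^2 / (2 * params$D)) {
    abort(sprintf(
      "Unstable time step: dt = %.3g exceeds the stability limit dx^2/(2D) = %.3g.",
      dt, dx^2 / (2 * params$D)))
  }
  nx <- max(2L, ceiling(grid$length / dx) + 1L)
  x0 <- min(sites) - (grid$length - diff(range(sites))) / 2
  x <- x0 + (seq_len(nx) - 1L) * dx
  site_node <- pmin(pmax(round((sites - x0) / dx) + 1L, 1L), nx)

  lam <- if (params$D > 0) params$D * dt / dx^2 else 0
  n_rel <- max(1L, as.integer(round(params$tau / dt)))
  dep_per_step <- (params$sigma_conc * params$d) / (n_rel * dx)  # uM per step

  conc <- rep(params$ca_basal, nx)
  mass0 <- sum(conc) * dx
  fire_step <- rep(NA_integer_, n_sites)   # step index at whose time the site fired
  rel_left <- rep(0L, n_sites)
  if (!is.na(trigger)) {
    fire_step[trigger] <- 0L
    rel_left[trigger] <- n_rel
  }
  n_steps <- max(1L, ceiling(grid$t_max / dt))
  snap_steps <- unique(c(0L, round(seq(1, n_steps, length.out = max(1, n_snapshots - 1)))))
  snaps <- list(list(t = 0, conc = conc))

  idx <- seq_len(nx)
  left <- c(1L, idx[-nx]); right <- c(idx[-1L], nx)  # mirror => zero-flux
  step <- 0L
  while (step < n_steps) {
    step <- step + 1L
    if (lam > 0) {
      conc <- conc + lam * (conc[left] + conc[right] - 2 * conc)
    }
    active <- rel_left > 0L
    if (any(active)) {
      nodes <- site_node[active]
      conc[nodes] <- conc[nodes] + dep_per_step
      rel_left[active] <- rel_left[active] - 1L
    }
    if (grid$boundary == "absorbing") {
      conc[c(1L, nx)] <- params$ca_basal
    }
    unfired <- which(is.na(fire_step))
    if (length(unfired)) {
      hit <- unfired[conc[site_node[unfired]] >= params$ca_threshold]
      if (length(hit)) {
        fire_step[hit] <- step
        rel_left[hit] <- n_rel
      }
    }
    if (step %in% snap_steps) {
      snaps[[length(snaps) + 1L]] <- list(t = step * dt, conc = conc)
    }
    if (!anyNA(fire_step) && !any(rel_left > 0L)) break
  }
  if (!identical(snaps[[length(snaps)]]$t, step * dt)) {
    snaps[[length(snaps) + 1L]] <- list(t = step * dt, conc = conc)
  }

  completed <- sum(!is.na(fire_step) & (fire_step + n_rel) <= step)
  mass_expected <- mass0 + params$sigma_conc * params$d * completed
  mass_final <- sum(conc) * dx
  mass_balance <- tibble::tibble(
    initial = mass0, released_expected = mass_expected - mass0,
    final = mass_final,
    rel_error = if (grid$boundary == "reflecting")
      abs(mass_final - mass_expected) / mass_expected else NA_real_
  )

  firings <- tibble::tibble(
    site = seq_len(n_sites),
    position_um = sites,
    t_fire_s = fire_step * dt
  )
  snapshots <- purrr::map_dfr(snaps, function(s) {
    tibble::tibble(t_s = s$t, x_um = x, ca_uM = s$conc)
  })
  propagated <- mean(!is.na(fire_step)) >= propagation_fraction

  out <- structure(
    list(firings = firings, snapshots = snapshots,
         propagated = propagated, mass_balance = mass_balance,
         params = params, grid = grid, trigger = trigger,
         n_steps_run = step),
    class = "fdf_sim"
  )
  vel <- estimate_velocity(out)
  out$estimated_velocity <- vel$velocity
  out$velocity_ok <- vel$ok
  out
}

#' Estimate front velocity from firing times
#'
#' Least-squares slope of distance-from-trigger versus firing time over the
#' trailing half of fired sites, discarding the initiation transient. Requires
#' at least three firings; otherwise the velocity is undefined and `ok` is
#' FALSE.
#'
#' @param result An `fdf_sim` object, or a data frame with columns
#'   `position_um` and `t_fire_s`.
#' @param trigger_position Origin for the distance coordinate; defaults to the
#'   triggered site's position when `result` is an `fdf_sim`.
#' @return A list with `velocity` (um/s, NA when undefined), `ok` (logical)
#'   and `n_used` (sites entering the fit).
#' @examples
#' f <- tibble::tibble(position_um = 2 * (0:9), t_fire_s = 0.1 * (0:9))
#' estimate_velocity(f)$velocity  # 20
#' @export
estimate_velocity <- function(result, trigger_position = NULL) {
  if (inherits(result, "fdf_sim")) {
    firings <- result$firings
    if (is.null(trigger_position) && !is.na(result$trigger)) {
      trigger_position <- result$params$site_positions[[result$trigger]]
    }
  } else {
    firings <- tibble::as_tibble(result)
  }
  fired <- firings[!is.na(firings$t_fire_s), , drop = FALSE]
  if (nrow(fired) < 3) {
    return(list(velocity = NA_real_, ok = FALSE, n_used = nrow(fired)))
  }
  if (is.null(trigger_position)) {
    trigger_position <- fired$position_um[[which.min(fired$t_fire_s)]]
  }
  fired$dist <- abs(fired$position_um - trigger_position)
  fired <- fired[order(fired$t_fire_s, fired$dist), , drop = FALSE]
  n <- nrow(fired)
  use <- fired[seq.int(floor(n / 2) + 1L, n), , drop = FALSE]
  if (nrow(use) < 3) use <- tail(fired, 3L)
  if (length(unique(use$t_fire_s)) < 2) {
    return(list(velocity = NA_real_, ok = FALSE, n_used = nrow(use)))
  }
  fit <- lm(dist ~ t_fire_s, data = use)
  list(velocity = unname(coef(fit)[["t_fire_s"]]), ok = TRUE, n_used = nrow(use))
}

#' Velocity-versus-diffusion scaling scan
#'
#' Runs the simulator at several diffusion coefficients (holding all other
#' parameters fixed) and fits the log-log regression slope of front velocity
#' against D. In the continuous regime the slope approaches 1/2 (Luther
#' scaling); in the saltatory regime it approaches 1. If the scan straddles
#' regimes the result is flagged and a slope is reported per regime.
#'
#' @param params An [fdf_params()] object (its `D` is ignored).
#' @param D_values At least four diffusion coefficients spanning at least one
#'   decade (um^2/s).
#' @param grid Optional function `function(params)` returning a [sim_grid()];
#'   default uses `sim_grid(params)` per run.
#' @param convention beta convention for regime labelling, see [compute_beta()].
#' @param ... Passed to [classify_regime()].
#' @return An object of class `fdf_scan`: list with `results` (tibble of D,
#'   beta, regime, velocity, propagated), `slopes` (tibble of regime, slope,
#'   n) and `mixed_regimes` (logical flag).
#' @export
velocity_scaling_scan <- function(params, D_values, grid = NULL,
                                  convention = "worked_example", ...) {
  if (length(D_values) < 4) {
    abort("`D_values` must contain at least four values.")
  }
  if (max(D_values) / min(D_values) < 10) {
    abort("`D_values` must span at least one decade.")
  }
  make_grid <- grid %||% sim_grid
  gam <- compute_gamma(params$sigma_conc, params$ca_threshold, params$ca_basal)
  rows <- purrr::map(sort(D_values), function(D) {
    p <- params; p$D <- D
    sim <- simulate_fdf(p, make_grid(p))
    beta <- compute_beta(D, params$tau, params$d, convention = convention)
    cls <- classify_regime(gam, beta, D, params$d, tau = params$tau, ...)
    tibble::tibble(D = D, beta = beta, regime = cls$regime,
                   velocity = sim$estimated_velocity,
                   propagated = sim$propagated)
  })
  results <- dplyr::bind_rows(rows)
  usable <- results[results$propagated & !is.na(results$velocity), , drop = FALSE]
  slopes <- usable |>
    dplyr::group_by(.data$regime) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(
      slope = unname(coef(lm(log(velocity) ~ log(D)))[[2]]),
      n = dplyr::n(), .groups = "drop")
  mixed <- length(unique(usable$regime)) > 1
  if (mixed) {
    warn("Scan crosses wave regimes; slopes are reported per regime.")
  }
  structure(list(results = results, slopes = slopes, mixed_regimes = mixed),
            class = "fdf_scan")
}

#' @export
print.fdf_scan <- function(x, ...) {
  cat("<fdf_scan>", nrow(x$results), "simulations",
      if (x$mixed_regimes) "(mixed regimes)" else "", "\n")
  print(x$slopes)
  invisible(x)
}

#' @rdname simulate_fdf
#' @param x,object An `fdf_sim` object.
#' @param ... Unused.
#' @method tidy fdf_sim
#' @export
tidy.fdf_sim <- function(x, ...) x$firings

#' @rdname simulate_fdf
#' @method glance fdf_sim
#' @export
glance.fdf_sim <- function(x, ...) {
  tibble::tibble(
    estimated_velocity = x$estimated_velocity,
    propagated = x$propagated,
    n_fired = sum(!is.na(x$firings$t_fire_s)),
    n_sites = nrow(x$firings),
    mass_rel_error = x$mass_balance$rel_error
  )
}

#' @rdname velocity_scaling_scan
#' @param x An `fdf_scan` object.
#' @param ... Unused.
#' @method tidy fdf_scan
#' @export
tidy.fdf_scan <- function(x, ...) x$results

#' @rdname velocity_scaling_scan
#' @method glance fdf_scan
#' @export
glance.fdf_scan <- function(x, ...) {
  tidyr::pivot_wider(x$slopes, names_from = "regime", values_from = "slope",
                     names_prefix = "slope_", id_cols = character()) |>
    dplyr::mutate(mixed_regimes = x$mixed_regimes)
}

#' @rdname simulate_fdf
#' @method autoplot fdf_sim
#' @export
autoplot.fdf_sim <- function(object, ...) {
  ggplot2::ggplot(object$snapshots,
                  ggplot2::aes(x = .data$x_um, y = .data$t_s, fill = .data$ca_uM)) +
    ggplot2::geom_raster() +
    ggplot2::geom_point(
      data = tidy(object)[!is.na(tidy(object)$t_fire_s), ],
      ggplot2::aes(x = .data$position_um, y = .data$t_fire_s),
      inherit.aes = FALSE, shape = 4, colour = "white") +
    ggplot2::scale_fill_viridis_c(name = "[Ca2+] (uM)") +
    ggplot2::labs(x = "position (um)", y = "time (s)",
                  title = "Fire-diffuse-fire wave",
                  subtitle = sprintf("v = %.3g um/s, propagated = %s",
                                     object$estimated_velocity, object$propagated))
}

#' @rdname velocity_scaling_scan
#' @param object An `fdf_scan` object.
#' @method autoplot fdf_scan
#' @export
autoplot.fdf_scan <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(x = .data$D, y = .data$velocity,
                               colour = .data$regime)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "D (um^2/s)", y = "front velocity (um/s)",
                  title = "Velocity scaling with diffusion coefficient")
}
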