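#' Build the co-indexed Gamma/D parameter grid
#'
#' Builds the register grid: `n_grid` points with Gamma spaced over
#' `[gamma_min, gamma_max]` (linear by default, geometric available) and the
#' diffusion coefficient spaced over `[D_min, D_max]`, co-indexed so the
#' order-preserving one-to-one mapping between D and the Gamma index is
#' explicit. `tau`, `d` and the threshold concentrations are held fixed.
#'
#' @param config A configuration list, see [calwave_config()].
#' @return A tibble with columns `gamma`, `D`, `tau`, `d`.
#' @export
register_grid <- function(config = calwave_config()) {
  n <- config$n_grid
  gam <- switch(config$spacing,
    linear = seq(config$gamma_min, config$gamma_max, length.out = n),
    geometric = exp(seq(log(config$gamma_min), log(config$gamma_max),
                        length.out = n)),
    abort("`spacing` must be \"linear\" or \"geometric\".")
  )
  tibble::tibble(
    gamma = gam,
    D = seq(config$D_min, config$D_max, length.out = n),
    tau = config$tau,
    d = config$d
  )
}

#' Build a Grover search register from a wave-parameter grid
#'
#' Classifies every grid point with [classify_regime()]; points classified
#' continuous form the solution subset `i_M`, everything else (saltatory,
#' mixed, failure) the failure subset `i_F`. The register is sorted by Gamma
#' (order-preserving index) and padded up to the next power of two with
#' failure entries, so padding can never add solutions.
#'
#' @param data A data frame with columns `gamma`, `D`, `tau`, `d` (and
#'   optionally a precomputed `beta`).
#' @param convention beta convention, see [compute_beta()].
#' @param ... Passed to [classify_regime()] (thresholds, bands).
#' @return An object of class `search_register`: the classified tibble
#'   (`index`, `gamma`, `D`, `beta`, `regime`, `is_solution`, `padding`) with
#'   attributes `n_qubits`, `N`, `M`. Supports [tidy()] and [glance()].
#' @examples
#' build_search_register(register_grid())
#' @export
build_search_register <- function(data, convention = "worked_example", ...) {
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0) abort("`data` must contain at least one grid point.")
  data <- data[order(data$gamma), , drop = FALSE]
  cls <- classify_waves(data, convention = convention, ...)
  n_real <- nrow(cls)
  n_qubits <- max(1L, ceiling(log2(n_real)))
  N <- 2L^n_qubits
  pad <- N - n_real
  reg <- tibble::tibble(
    index = 0:(N - 1L),
    gamma = c(cls$gamma, rep(NA_real_, pad)),
    D = c(cls$D, rep(NA_real_, pad)),
    beta = c(cls$beta, rep(NA_real_, pad)),
    regime = factor(
      c(as.character(cls$regime), rep("failure", pad)),
      levels = levels(cls$regime)),
    model_velocity = c(cls$model_velocity, rep(NA_real_, pad)),
    is_solution = c(cls$regime == "continuous", rep(FALSE, pad)),
    padding = c(rep(FALSE, n_real), rep(TRUE, pad))
  )
  M <- sum(reg$is_solution)
  if (M == 0) warn("No grid point classifies as continuous: empty solution set.")
  structure(list(register = reg, n_qubits = n_qubits, N = N, M = M),
            class = "search_register")
}

#' @export
print.search_register <- function(x, ...) {
  cat("<search_register> N =", x$N, "(", x$n_qubits, "qubits ), M =", x$M,
      "continuous solutions\n")
  print(x$register, n = 6)
  invisible(x)
}

#' @rdname build_search_register
#' @param x A `search_register`.
#' @method tidy search_register
#' @export
tidy.search_register <- function(x, ...) x$register

#' @rdname build_search_register
#' @method glance search_register
#' @export
glance.search_register <- function(x, ...) {
  tibble::tibble(N = x$N, M = x$M, n_qubits = x$n_qubits,
                 n_padding = sum(x$register$padding))
}

#' Algorithmic search-time bound
#'
#' The order bound `ceiling(sqrt(D_max / D_C))` on the number of queries
#' needed to locate the continuous-wave diffusion coefficient, alongside the
#' exact Grover iteration count for a realized register when its size is
#' supplied: `floor(pi / (4 asin(sqrt(M/N))))`, the count at which the
#' statevector success probability peaks (e.g. 3 for N = 64, M = 4).
#'
#' @param D_max Largest diffusion coefficient in the scanned range (um^2/s).
#' @param D_C Continuous-wave diffusion coefficient, `0 < D_C <= D_max`.
#' @param N,M Optional realized register size and solution count.
#' @return A tibble with `order_bound` and (when N, M given) `grover_count`.
#' @examples
#' algorithmic_search_time(60, 15)           # bound 2
#' algorithmic_search_time(60, 15, N = 64, M = 4)
#' @export
algorithmic_search_time <- function(D_max, D_C, N = NULL, M = NULL) {
  if (any(D_C <= 0)) abort("`D_C` must be > 0.")
  if (any(D_max < D_C)) abort("`D_max` must be >= `D_C`.")
  out <- tibble::tibble(order_bound = ceiling(sqrt(D_max / D_C)))
  if (!is.null(N) && !is.null(M)) {
    if (M < 1) abort("`M` must be >= 1 for a Grover count.")
    out$grover_count <- max(0L, as.integer(floor(pi / (4 * asin(sqrt(M / N))))))
  }
  out
}

#' Check the quadratic speed-up relations
#'
#' Records, without enforcing, the two quadratic relations: the velocity
#' relation `v_C >= v_S^2` (a numeric check in um/s; as printed it compares
#' quantities of different dimension, so it is only meaningful in these fixed
#' units and is flagged, never asserted) and the query relation that the
#' Grover count is at most on the order of the square root of the classical
#' count (`grover^2 <= 4 * classical`).
#'
#' @param v_S Saltatory velocity (um/s).
#' @param v_C Continuous velocity (um/s).
#' @param classical_queries Expected classical query count.
#' @param grover_queries Grover query count.
#' @return A one-row tibble with the inputs, `velocity_quadratic_holds`,
#'   `query_quadratic_holds` and `quadratic_relation_holds` (both).
#' @examples
#' verify_quadratic_relations(7.5, 69, 2.5, 1)
#' @export
verify_quadratic_relations <- function(v_S, v_C, classical_queries,
                                       grover_queries) {
  vel_ok <- v_C >= v_S^2
  qry_ok <- grover_queries^2 <= 4 * classical_queries
  tibble::tibble(
    v_saltatory = v_S, v_continuous = v_C,
    velocity_quadratic_holds = vel_ok,
    classical_queries = classical_queries,
    grover_queries = grover_queries,
    query_quadratic_holds = qry_ok,
    quadratic_relation_holds = vel_ok & qry_ok
  )
}

#' Run the full wave-to-search pipeline
#'
#' Sweeps the configured parameter grid, classifies every point, builds the
#' padded search register, runs Grover's search for the continuous-wave
#' solutions and the exact classical baseline, evaluates the search-time
#' bound and the quadratic relations, and reproduces the worked-example
#' table of printed (beta, v) values. Deterministic given `seed`.
#'
#' @param config A configuration list, see [calwave_config()].
#' @param seed Integer seed for the Grover measurement.
#' @return An object of class `correspondence_report`. Supports [glance()]
#'   and [write_report()].
#' @examples
#' rep <- run_end_to_end(seed = 1)
#' glance(rep)
#' @export
run_end_to_end <- function(config = calwave_config(), seed = 1) {
  grid <- register_grid(config)
  grid$sigma_conc <- config$sigma_conc
  grid$ca_threshold <- config$ca_threshold
  grid$ca_basal <- config$ca_basal
  reg <- build_search_register(
    grid[, c("gamma", "D", "tau", "d")],
    beta_lo = config$beta_lo, beta_hi = config$beta_hi,
    gamma_band = config$gamma_band)

  worked <- classify_waves(
    tibble::tibble(
      D = config$worked_examples$D,
      tau = config$worked_examples$tau,
      d = config$worked_examples$d,
      gamma = compute_gamma(config$sigma_conc, config$ca_threshold,
                            config$ca_basal)),
    gamma_band = c(0, Inf), d_fail = Inf)

  no_solution <- reg$M == 0
  if (no_solution) {
    grover <- NULL; queries <- NULL; stime <- NULL; relations <- NULL
  } else {
    solutions <- reg$register$index[reg$register$is_solution]
    grover <- grover_search(reg$n_qubits, solutions, seed = seed)
    queries <- query_count_comparison(reg$n_qubits, reg$M)
    cont <- reg$register$regime == "continuous" & !reg$register$padding
    stime <- algorithmic_search_time(
      D_max = max(reg$register$D, na.rm = TRUE),
      D_C = min(reg$register$D[cont], na.rm = TRUE),
      N = reg$N, M = reg$M)
    v_S <- worked$model_velocity[worked$regime == "saltatory"][1]
    v_C <- worked$model_velocity[worked$regime == "continuous"][1]
    relations <- verify_quadratic_relations(
      v_S, v_C, queries$classical_expected_queries, queries$grover_queries)
  }
  structure(
    list(register = reg, grover = grover, queries = queries,
         search_time = stime, relations = relations,
         worked_examples = worked, config = config, seed = seed,
         no_solution = no_solution),
    class = "correspondence_report")
}

#' @export
print.correspondence_report <- function(x, ...) {
  cat("<correspondence_report> seed =", x$seed, "\n")
  if (x$no_solution) {
    cat("  NO SOLUTION: no grid point classified continuous.\n")
  } else {
    cat(sprintf("  register N = %d, M = %d; Grover k = %d, P(success) = %.4f, measured index = %d\n",
                x$register$N, x$register$M, x$grover$iterations_used,
                x$grover$success_probability, x$grover$measured))
    cat(sprintf("  classical E[queries] = %.2f, grover queries = %d, bound O(sqrt(D_max/D_C)) = %d\n",
                x$queries$classical_expected_queries, x$queries$grover_queries,
                x$search_time$order_bound))
    cat(sprintf("  quadratic relations hold: %s\n",
                x$relations$quadratic_relation_holds))
  }
  cat("  worked examples:\n")
  print(x$worked_examples)
  invisible(x)
}

#' @rdname run_end_to_end
#' @param x A `correspondence_report`.
#' @param ... Unused.
#' @method glance correspondence_report
#' @export
glance.correspondence_report <- function(x, ...) {
  if (x$no_solution) {
    return(tibble::tibble(N = x$register$N, M = 0L, no_solution = TRUE))
  }
  tibble::tibble(
    N = x$register$N, M = x$register$M,
    grover_iterations = x$grover$iterations_used,
    success_probability = x$grover$success_probability,
    measured_index = x$grover$measured,
    classical_queries = x$queries$classical_expected_queries,
    grover_queries = x$queries$grover_queries,
    search_time_bound = x$search_time$order_bound,
    quadratic_relation_holds = x$relations$quadratic_relation_holds,
    no_solution = FALSE
  )
}

#' Write report artifacts
#'
#' Writes `register.csv` (index, gamma, D, beta, regime, is_solution) and
#' `report.json` (summary, worked examples, configuration echo) to a
#' directory.
#'
#' @param report A `correspondence_report`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "correspondence_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(report$register$register, file.path(dir, "register.csv"),
            row.names = FALSE)
  summary <- c(
    as.list(glance(report)),
    list(worked_examples = report$worked_examples,
         seed = report$seed,
         config = report$config[setdiff(names(report$config), "worked_examples")])
  )
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname run_end_to_end
#' @param object A `correspondence_report`.
#' @method autoplot correspondence_report
#' @export
autoplot.correspondence_report <- function(object, ...) {
  reg <- object$register$register
  reg <- reg[!reg$padding, , drop = FALSE]
  ggplot2::ggplot(reg, ggplot2::aes(x = .data$index, y = .data$beta,
                                    colour = .data$regime,
                                    shape = .data$is_solution)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "register index (Gamma-ordered)", y = "beta",
                  title = "Gamma-indexed search register",
                  shape = "solution (continuous)")
}
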