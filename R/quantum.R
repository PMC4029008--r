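#' Dense statevector over n qubits
#'
#' A pure quantum state stored as a complex amplitude vector of length `2^n`
#' over the computational basis, indexed `0 .. 2^n - 1` with qubit 1 the most
#' significant bit. Defaults to `|0...0>`.
#'
#' @param n_qubits Integer >= 1.
#' @param amplitudes Optional complex vector of length `2^n`; normalized if
#'   its norm differs from 1 by more than 1e-12 it is rejected.
#' @return An object of class `quantum_state`.
#' @examples
#' quantum_state(2)
#' @export
quantum_state <- function(n_qubits, amplitudes = NULL) {
  n_qubits <- as.integer(n_qubits)
  if (n_qubits < 1) abort("`n_qubits` must be >= 1.")
  N <- 2L^n_qubits
  if (is.null(amplitudes)) {
    amplitudes <- complex(real = c(1, rep(0, N - 1)))
  }
  amplitudes <- as.complex(amplitudes)
  if (length(amplitudes) != N) {
    abort(sprintf("`amplitudes` must have length 2^%d = %d.", n_qubits, N))
  }
  nrm <- sqrt(sum(Mod(amplitudes)^2))
  if (abs(nrm - 1) > 1e-12) {
    abort(sprintf("State norm %.15g is not 1 (tolerance 1e-12).", nrm))
  }
  structure(list(n_qubits = n_qubits, amplitudes = amplitudes),
            class = "quantum_state")
}

#' @export
print.quantum_state <- function(x, ...) {
  cat("<quantum_state>", x$n_qubits, "qubits\n")
  N <- length(x$amplitudes)
  show <- which(Mod(x$amplitudes) > 1e-12)
  labs <- basis_labels(x$n_qubits)
  for (i in head(show, 8)) {
    cat(sprintf("  |%s>  % .6f %+.6fi\n", labs[[i]],
                Re(x$amplitudes[[i]]), Im(x$amplitudes[[i]])))
  }
  if (length(show) > 8) cat("  ...", length(show) - 8, "more\n")
  invisible(x)
}

#' Basis-state labels
#'
#' @param n_qubits Integer >= 1.
#' @return Character vector of the `2^n` bit strings, most significant qubit
#'   first.
#' @export
basis_labels <- function(n_qubits) {
  N <- 2L^n_qubits
  vapply(0:(N - 1L), function(i) {
    paste(rev(as.integer(intToBits(i))[seq_len(n_qubits)]), collapse = "")
  }, character(1))
}

#' Hadamard transform on every qubit
#'
#' Applies `H^{(x)n}`; on `|0...0>` this yields the uniform superposition with
#' amplitudes `1/sqrt(N)`. Implemented as a fast Walsh-Hadamard butterfly.
#'
#' @param state A [quantum_state()].
#' @return The transformed `quantum_state`.
#' @examples
#' hadamard_all(quantum_state(2))$amplitudes  # all 1/2
#' @export
hadamard_all <- function(state) {
  stopifnot(inherits(state, "quantum_state"))
  a <- state$amplitudes
  N <- length(a)
  h <- 1L
  while (h < N) {
    for (start in seq(1L, N, by = 2L * h)) {
      i <- start:(start + h - 1L)
      x <- a[i]; y <- a[i + h]
      a[i] <- x + y
      a[i + h] <- x - y
    }
    h <- 2L * h
  }
  state$amplitudes <- a / sqrt(N)
  state
}

#' Oracle phase flip
#'
#' Multiplies the amplitude of each marked basis state by -1: the
#' phase-kickback-free form of the indicator-function oracle theta(x). The
#' explicit ancilla construction (an extra qubit prepared in
#' `(|0> - |1>)/sqrt(2)` and flipped conditionally) is equivalent up to the
#' untouched ancilla and is exercised in the test-suite oracle.
#'
#' @param state A [quantum_state()].
#' @param solutions Integer vector of marked basis indices in
#'   `0 .. 2^n - 1` (may be empty).
#' @return The phase-flipped `quantum_state`.
#' @export
apply_oracle <- function(state, solutions) {
  stopifnot(inherits(state, "quantum_state"))
  N <- length(state$amplitudes)
  solutions <- as.integer(solutions)
  if (length(solutions) && (any(solutions < 0) || any(solutions >= N))) {
    abort(sprintf("`solutions` must lie in 0 .. %d.", N - 1L))
  }
  if (length(solutions)) {
    state$amplitudes[solutions + 1L] <- -state$amplitudes[solutions + 1L]
  }
  state
}

#' Grover diffusion operator
#'
#' Applies `H^{(x)n} (2|0><0| - I) H^{(x)n}`, the inversion of every
#' amplitude about the mean amplitude. The uniform superposition is its fixed
#' point.
#'
#' @param state A [quantum_state()].
#' @return The reflected `quantum_state`.
#' @export
grover_diffusion <- function(state) {
  stopifnot(inherits(state, "quantum_state"))
  a <- state$amplitudes
  state$amplitudes <- 2 * mean(a) - a
  state
}

#' Grover's search on a dense statevector
#'
#' Initializes the uniform superposition, applies `iterations` rounds of
#' oracle + diffusion, reports the probability mass on the solution set, and
#' samples one measurement. With `iterations = "auto"` the count is
#' `k = round(pi / (4 asin(sqrt(M/N))) - 1/2)` (round half up, floored at 0),
#' which maximizes the closed-form success probability
#' `sin^2((2k+1) asin(sqrt(M/N)))`.
#'
#' @param n_qubits Register size n (N = 2^n).
#' @param solutions Nonempty integer vector of solution indices in
#'   `0 .. 2^n - 1`.
#' @param iterations `"auto"` or a nonnegative integer.
#' @param seed Optional integer seed for the measurement sample.
#' @return A list with `measured` (basis index), `success_probability`,
#'   `iterations_used`, `state` (final `quantum_state`) and
#'   `theoretical_probability` (closed form).
#' @examples
#' grover_search(2, 3, seed = 1)  # N = 4, one iteration, certainty
#' @export
grover_search <- function(n_qubits, solutions, iterations = "auto", seed = NULL) {
  solutions <- as.integer(solutions)
  if (length(solutions) == 0) {
    abort("`solutions` is empty: the search has no target (M = 0).")
  }
  N <- 2L^as.integer(n_qubits)
  if (any(solutions < 0) || any(solutions >= N)) {
    abort(sprintf("`solutions` must lie in 0 .. %d.", N - 1L))
  }
  M <- length(unique(solutions))
  theta <- asin(sqrt(M / N))
  if (identical(iterations, "auto")) {
    k <- max(0L, as.integer(floor(pi / (4 * theta) - 0.5 + 0.5)))  # round half up
  } else {
    k <- as.integer(iterations)
    if (k < 0) abort("`iterations` must be >= 0.")
  }
  state <- hadamard_all(quantum_state(n_qubits))
  for (i in seq_len(k)) {
    state <- grover_diffusion(apply_oracle(state, solutions))
  }
  probs <- Mod(state$amplitudes)^2
  success <- sum(probs[unique(solutions) + 1L])
  draw <- function() sample.int(N, 1L, prob = probs) - 1L
  measured <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  list(
    measured = measured,
    success_probability = success,
    iterations_used = k,
    theoretical_probability = sin((2 * k + 1) * theta)^2,
    state = state
  )
}

#' Classical versus Grover query counts
#'
#' Classical cost is the exact expected number of sequential probes until the
#' first hit when M targets hide uniformly among N items, accumulated term by
#' term over the hitting-time distribution (it equals `(N+1)/(M+1)`). The
#' Grover cost is reported in two conventions: `grover_queries`, the standard
#' query-complexity count `ceiling((pi/4) sqrt(N/M))` used for scaling
#' comparisons, and `iterations_auto`, the measurement-optimal iteration
#' count used by [grover_search()] (whose -1/2 offset makes it smaller at
#' tiny N, e.g. 1 for N = 4).
#'
#' @param n_qubits Register size n (N = 2^n).
#' @param M Number of solutions, `1 <= M <= N`.
#' @return A tibble with `N`, `M`, `classical_expected_queries`,
#'   `grover_queries`, `iterations_auto` and `speedup` (classical / grover).
#' @examples
#' query_count_comparison(2, 1)  # classical 2.5
#' @export
query_count_comparison <- function(n_qubits, M = 1) {
  N <- 2L^as.integer(n_qubits)
  M <- as.integer(M)
  if (M < 1 || M > N) abort("`M` must satisfy 1 <= M <= N.")
  # exact enumeration of P(first hit at probe j), j = 1 .. N - M + 1
  expected <- 0
  p_no_hit <- 1
  for (j in seq_len(N - M + 1L)) {
    p_hit_j <- p_no_hit * M / (N - j + 1L)
    expected <- expected + j * p_hit_j
    p_no_hit <- p_no_hit * (N - M - j + 1L) / (N - j + 1L)
  }
  theta <- asin(sqrt(M / N))
  tibble::tibble(
    N = N, M = M,
    classical_expected_queries = expected,
    grover_queries = ceiling((pi / 4) * sqrt(N / M)),
    iterations_auto = max(0L, as.integer(floor(pi / (4 * theta)))),
    speedup = expected / ceiling((pi / 4) * sqrt(N / M))
  )
}
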