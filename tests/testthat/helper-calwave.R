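# Independent dense-matrix oracles for the statevector operations.

uniform_state <- function(n) hadamard_all(quantum_state(n))

# 2|psi><psi| - I built explicitly from the uniform state vector.
dense_diffusion_matrix <- function(n) {
  N <- 2^n
  psi <- rep(1 / sqrt(N), N)
  2 * (psi %*% t(psi)) - diag(N)
}

# Explicit ancilla-based oracle: the register is joined with one extra qubit
# prepared in (|0> - |1>)/sqrt(2) (least significant), and a controlled-X
# flips the ancilla for solution indices. Returns the register amplitudes
# after factoring the (untouched) ancilla back out.
ancilla_oracle <- function(amps, solutions) {
  N <- length(amps)
  minus <- c(1, -1) / sqrt(2)
  joint <- as.vector(t(outer(amps, minus)))  # index 2x + ancilla_bit + 1
  for (x in solutions) {
    i0 <- 2 * x + 1
    joint[c(i0, i0 + 1)] <- joint[c(i0 + 1, i0)]
  }
  # ancilla still in (|0> - |1>)/sqrt(2); project it out
  reg <- joint[seq(1, 2 * N, by = 2)] / minus[[1]]
  reg
}

random_state <- function(n, seed) {
  withr::with_seed(seed, {
    v <- complex(real = rnorm(2^n), imaginary = rnorm(2^n))
    quantum_state(n, v / sqrt(sum(Mod(v)^2)))
  })
}

# Small fast fire-diffuse-fire configuration used across tests.
small_fdf <- function(D, gamma = 10, n_sites = 10, d = 2, tau = 0.04) {
  fdf_params(D = D, d = d, sigma_conc = gamma * 0.5, tau = tau,
             ca_threshold = 0.6, ca_basal = 0.1, n_sites = n_sites)
}

loglog_slope <- function(x, y) unname(coef(lm(log(y) ~ log(x)))[[2]])
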