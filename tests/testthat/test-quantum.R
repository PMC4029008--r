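test_that("the Hadamard layer builds uniform superpositions and is an involution", {
  u <- hadamard_all(quantum_state(2))
  expect_equal(u$amplitudes, complex(real = rep(0.5, 4)))
  one <- hadamard_all(quantum_state(1, c(0, 1)))
  expect_equal(one$amplitudes, complex(real = c(1, -1) / sqrt(2)))
  for (n in 1:5) {
    s <- random_state(n, seed = n)
    back <- hadamard_all(hadamard_all(s))
    expect_equal(back$amplitudes, s$amplitudes, tolerance = 1e-12)
  }
  expect_error(quantum_state(2, c(1, 1, 0, 0)), "norm")
})

test_that("the oracle phase-flips marked states only and squares to identity", {
  u <- uniform_state(2)
  flipped <- apply_oracle(u, 2)
  expect_equal(flipped$amplitudes, complex(real = c(0.5, 0.5, -0.5, 0.5)))
  expect_equal(apply_oracle(flipped, 2)$amplitudes, u$amplitudes)
  expect_equal(apply_oracle(u, integer(0))$amplitudes, u$amplitudes)
  expect_error(apply_oracle(u, 4), "0 .. 3")
})

test_that("the phase-flip oracle equals the explicit ancilla construction", {
  for (n in 1:4) {
    sols <- list(0, c(1, 2), seq_len(2^n) - 1)
    for (sol in sols) {
      sol <- sol[sol < 2^n]
      s <- random_state(n, seed = 10 * n + length(sol))
      via_phase <- apply_oracle(s, sol)$amplitudes
      via_ancilla <- ancilla_oracle(s$amplitudes, sol)
      expect_equal(via_ancilla, via_phase, tolerance = 1e-12)
    }
  }
})

test_that("diffusion inverts about the mean, fixes the uniform state, and is unitary", {
  u <- uniform_state(3)
  expect_equal(grover_diffusion(u)$amplitudes, u$amplitudes, tolerance = 1e-12)
  for (n in c(2, 4, 6)) {
    s <- random_state(n, seed = n)
    direct <- grover_diffusion(s)$amplitudes
    via_matrix <- as.vector(dense_diffusion_matrix(n) %*% s$amplitudes)
    expect_equal(direct, via_matrix, tolerance = 1e-12)
    expect_equal(sum(Mod(direct)^2), 1, tolerance = 1e-12)
    # G G^T = I on the dense form
    G <- dense_diffusion_matrix(n)
    expect_equal(G %*% t(G), diag(2^n), tolerance = 1e-12)
  }
})

test_that("norm is preserved through full Grover iterations", {
  s <- uniform_state(5)
  for (i in 1:8) s <- grover_diffusion(apply_oracle(s, c(3, 17)))
  expect_equal(sum(Mod(s$amplitudes)^2), 1, tolerance = 1e-12)
})

test_that("search success probability matches the closed form sin^2((2k+1) theta)", {
  # exhaustive over all register sizes n <= 5 and all solution counts
  for (n in 1:5) {
    N <- 2^n
    for (M in 1:N) {
      res <- grover_search(n, seq_len(M) - 1, seed = 1)
      theta <- asin(sqrt(M / N))
      expect_equal(res$success_probability,
                   sin((2 * res$iterations_used + 1) * theta)^2,
                   tolerance = 1e-10)
    }
  }
  # N = 4, M = 1: one iteration reaches certainty
  res4 <- grover_search(2, 3, seed = 7)
  expect_equal(res4$iterations_used, 1)
  expect_equal(res4$success_probability, 1, tolerance = 1e-12)
  expect_equal(res4$measured, 3)
  # N = 8, M = 1: two iterations, probability from the dense statevector
  res8 <- grover_search(3, 5, seed = 7)
  expect_equal(res8$iterations_used, 2)
  expect_equal(res8$success_probability, 0.9453125, tolerance = 1e-12)
  # M = N: zero iterations suffice
  resN <- grover_search(2, 0:3, seed = 1)
  expect_equal(resN$iterations_used, 0)
  expect_equal(resN$success_probability, 1)
  expect_error(grover_search(2, integer(0)), "M = 0")
})

test_that("measurement sampling is reproducible bit-exactly under a fixed seed", {
  a <- grover_search(4, c(2, 9), seed = 123)
  b <- grover_search(4, c(2, 9), seed = 123)
  expect_identical(a$measured, b$measured)
  expect_identical(a$state$amplitudes, b$state$amplitudes)
})

test_that("classical and Grover query counts show the quadratic separation", {
  q4 <- query_count_comparison(2, 1)
  expect_equal(q4$classical_expected_queries, 2.5)   # exact enumeration (N+1)/2
  expect_equal(q4$iterations_auto, 1)
  q10 <- query_count_comparison(10, 1)
  expect_lte(q10$grover_queries, ceiling((pi / 4) * sqrt(1024)))
  # enumeration agrees with the closed form (N+1)/(M+1) for several M
  for (M in c(1, 3, 7)) {
    q <- query_count_comparison(3, M)
    expect_equal(q$classical_expected_queries, (8 + 1) / (M + 1))
  }
  # ratio grows as sqrt(N) across N = 4 .. 1024
  qs <- dplyr::bind_rows(lapply(2:10, query_count_comparison, M = 1))
  ratio <- qs$classical_expected_queries / qs$grover_queries
  expect_lt(abs(loglog_slope(qs$N, ratio) - 0.5), 0.05)
})

test_that("Bell states are orthonormal and match their definitions", {
  labels <- c("00", "01", "10", "11")
  states <- lapply(labels, bell_state)
  expect_equal(states[[1]]$amplitudes,
               complex(real = c(1, 0, 0, 1) / sqrt(2)))
  for (i in 1:4) for (j in 1:4) {
    ip <- sum(Conj(states[[i]]$amplitudes) * states[[j]]$amplitudes)
    expect_equal(Mod(ip), as.numeric(i == j), tolerance = 1e-12)
  }
})

test_that("superdense coding round-trips all four two-bit messages", {
  for (b in c("00", "01", "10", "11")) {
    dec <- superdense_decode(superdense_encode(b))
    expect_equal(dec$bits, b)
    expect_true(dec$deterministic)
    expect_equal(dec$probability, 1, tolerance = 1e-12)
  }
  # a non-Bell input still yields the argmax outcome, flagged non-deterministic
  dec <- superdense_decode(quantum_state(2, c(1, 0, 0, 0)))
  expect_false(dec$deterministic)
  expect_equal(dec$probability, 0.5, tolerance = 1e-12)
})

test_that("the monomer conformation oracle marks |110> only", {
  all_bits <- do.call(expand.grid, rep(list(0:1), 3))
  labels <- apply(all_bits, 1, paste, collapse = "")
  theta <- vapply(labels, theta_conformation, integer(1))
  expect_equal(sum(theta), 1L)
  expect_equal(unname(theta[labels == "110"]), 1L)
  expect_equal(theta_conformation("100"), 0L)  # primed but closed
  # configurable conducting set
  expect_equal(theta_conformation("100", conducting = c("100", "110")), 1L)
  expect_equal(count_primed_configurations(4), 4)
  expect_equal(count_primed_configurations(1), 1)
  expect_error(count_primed_configurations(0))
})
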