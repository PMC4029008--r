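test_that("gamma is the released-over-threshold concentration ratio", {
  expect_equal(compute_gamma(0, 0.6, 0.1), 0)
  expect_equal(compute_gamma(0.5, 0.6, 0.1), 1)
  expect_equal(compute_gamma(5, 0.6, 0.1), 10)
  expect_error(compute_gamma(5, 0.1, 0.1), "exceed")
  expect_error(compute_gamma(-1, 0.6, 0.1))
})

test_that("beta reproduces all four published worked values under the default convention", {
  cases <- tibble::tribble(
    ~D,   ~tau,  ~d,    ~beta,
    190,  0.04,  2,     1.9,
    15,   0.04,  2,     0.15,
    190,  0.04,  0.02,  19000,
    15,   0.04,  0.02,  1500
  )
  expect_equal(compute_beta(cases$D, cases$tau, cases$d), cases$beta,
               tolerance = 1e-12)
  # the literal printed form disagrees with every worked value
  expect_equal(compute_beta(190, 0.04, 2, convention = "as_printed"),
               (190 / 0.04) / 4)
  expect_false(isTRUE(all.equal(
    compute_beta(190, 0.04, 2, convention = "as_printed"), 1.9)))
  expect_error(compute_beta(-1, 0.04, 2))
})

test_that("velocity laws reproduce the worked examples and are monotone in D", {
  expect_equal(saltatory_velocity(15, 2), 7.5)
  expect_equal(saltatory_velocity(0, 2), 0)
  expect_equal(saltatory_velocity(20, 2, 0.5), 5)
  expect_equal(continuous_velocity(190, 0.04), sqrt(190 / 0.04))
  expect_lt(abs(continuous_velocity(190, 0.04) - 69), 0.5)
  expect_lt(abs(continuous_velocity(15, 0.04) - 19), 0.5)
  expect_equal(continuous_velocity(0, 0.04), 0)
  D <- seq(1, 500, length.out = 50)
  expect_true(all(diff(saltatory_velocity(D, 2)) >= 0))
  expect_true(all(diff(continuous_velocity(D, 0.04)) >= 0))
  expect_error(saltatory_velocity(15, 0))
  expect_error(continuous_velocity(15, 0))
})

test_that("diffusion_from_velocity inverts the velocity laws exactly", {
  v_c <- continuous_velocity(190, 0.04, gamma_factor = 3)
  expect_equal(diffusion_from_velocity(v_c, "continuous", tau = 0.04,
                                       gamma = 3, geometry_factor = 1) * 9,
               190 * 9)  # f/Gamma collapse: (v*f/Gamma)^2 * tau
  # printed worked-example inversions
  expect_lt(abs(diffusion_from_velocity(69, "continuous", tau = 0.04,
                                        gamma = 1) - 190), 1)
  expect_equal(diffusion_from_velocity(7.5, "saltatory", d = 2, gamma = 1), 15)
  # exact algebraic round trip with unit collapse factors
  for (D in c(3, 42, 190)) {
    expect_equal(diffusion_from_velocity(
      continuous_velocity(D, 0.04), "continuous", tau = 0.04, gamma = 1), D)
    expect_equal(diffusion_from_velocity(
      saltatory_velocity(D, 2), "saltatory", d = 2, gamma = 1), D)
  }
  expect_error(diffusion_from_velocity(5, "saltatory", d = 2, gamma = 0))
})

test_that("gamma_from_velocity recovers Gamma under the matching beta convention", {
  D <- 15; d <- 2; tau <- 0.04; gam <- 7
  # saltatory: v = (D/d) Gamma / g; with worked-example beta the identity is exact
  v <- saltatory_velocity(D, d, geometry_factor = gam)
  beta_we <- compute_beta(D, tau, d)
  expect_equal(gamma_from_velocity(v, "saltatory", beta = beta_we, d = d,
                                   tau = tau), gam)
  # doubling the geometry factor doubles Gamma_S
  expect_equal(gamma_from_velocity(v, "saltatory", beta = beta_we, d = d,
                                   tau = tau, geometry_factor = 2), 2 * gam)
  # continuous: under the as-printed beta, Gamma_C returns sqrt(Gamma)
  v_c <- continuous_velocity(190, tau, gamma_factor = sqrt(gam))
  beta_ap <- compute_beta(190, tau, d, convention = "as_printed")
  expect_equal(gamma_from_velocity(v_c, "continuous", beta = beta_ap, d = d),
               sqrt(gam))
  expect_equal(gamma_from_velocity(0, "continuous", beta = 1, d = 2), 0)
  expect_error(gamma_from_velocity(1, "continuous", beta = 0, d = 2))
})

test_that("regime classification follows the beta thresholds and failure rules", {
  # intracluster continuous despite globally 'saltatory-looking' D
  expect_equal(as.character(
    classify_regime(10, 19000, D = 190, d = 0.02, tau = 0.04)$regime),
    "continuous")
  # large spacing fails outright
  expect_equal(as.character(
    classify_regime(10, 1.9, D = 190, d = 4, tau = 0.04)$regime), "failure")
  # printed saltatory example
  cls <- classify_regime(10, 0.15, D = 15, d = 2, tau = 0.04)
  expect_equal(as.character(cls$regime), "saltatory")
  expect_equal(cls$model_velocity, 7.5)
  # small D with saltatory beta fails; the same D with continuous beta does not
  expect_equal(as.character(
    classify_regime(10, 0.15, D = 5, d = 2, tau = 0.04)$regime), "failure")
  # Gamma out of band fails
  expect_equal(as.character(
    classify_regime(1e5, 1.9, D = 190, d = 2, tau = 0.04)$regime), "failure")
  # intermediate beta is mixed, with no single model velocity
  mid <- classify_regime(10, 0.7, D = 70, d = 2, tau = 0.04)
  expect_equal(as.character(mid$regime), "mixed")
  expect_true(is.na(mid$model_velocity))
})

test_that("classify_waves appends tidy columns and accepts raw concentrations", {
  df <- tibble::tibble(D = c(190, 15), tau = 0.04, d = 2,
                       sigma_conc = 5, ca_threshold = 0.6, ca_basal = 0.1)
  out <- classify_waves(df)
  expect_s3_class(out, "tbl_df")
  expect_equal(out$gamma, c(10, 10))
  expect_equal(out$beta, c(1.9, 0.15), tolerance = 1e-12)
  expect_equal(as.character(out$regime), c("continuous", "saltatory"))
  expect_equal(out$model_velocity, c(sqrt(190 / 0.04), 7.5))
  expect_error(classify_waves(tibble::tibble(D = 1)), "columns")
})

test_that("the printed velocity pair satisfies the greater-than-a-power-of-2 relation", {
  # numeric check in um/s units only (dimensionally inconsistent as a law)
  expect_true(69 >= 7.5^2)
  expect_true(verify_quadratic_relations(7.5, 69, 2.5, 1)$velocity_quadratic_holds)
})
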