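test_that("the Sestak-Berggren function matches its closed form", {
  expect_equal(sestak_berggren(0.5, 1, 1), 0.25)
  expect_equal(sestak_berggren(0, 0.5, 2), 0)
  expect_equal(sestak_berggren(1, 0.5, 2), 0)
  expect_equal(sestak_berggren(0.5, 0, 1), 0.5) # M = 0: reaction-order form
  expect_equal(sestak_berggren(0, 0, 1), 1)     # 0^0 convention
  expect_error(sestak_berggren(1.2, 1, 1), "\\[0, 1\\]")
  expect_error(sestak_berggren(-0.1, 1, 1), "\\[0, 1\\]")
})

test_that("Arrhenius rate constants evaluate correctly", {
  s <- step_kinetics(0, 5e10, 0.5, 1)
  expect_equal(arrhenius_rate_constant(s, 400), 5e10) # zero exponent
  s2 <- step_kinetics(1e5, 1e10, 0.5, 1)
  expect_equal(arrhenius_rate_constant(s2, 500),
               1e10 * exp(-1e5 / (8.314 * 500)))
  expect_error(arrhenius_rate_constant(s2, -10), "positive")
  # strictly increasing in T for constant positive E
  Ts <- seq(300, 800, by = 50)
  expect_true(all(diff(arrhenius_rate_constant(s2, Ts)) > 0))
})

test_that("temperature-dependent activation energies evaluate and clamp", {
  E <- activation_energy_poly(b = -20000, c = -1e6, T_min = 450, T_max = 650)
  Tt <- c(450, 500, 650)
  expect_equal(E_at(E, Tt), -8.314 * (-20000 + 2 * -1e6 / Tt))
  expect_error(E_at(E, 400, clamp = FALSE), "window")
  expect_equal(E_at(E, 400), E_at(E, 450)) # clamped to edge
  expect_error(activation_energy_poly(b = 20000, c = 1e6, 450, 650),
               "positive")
})

test_that("conversion from mass is (m0 - m)/m0 with mass gain rejected", {
  expect_equal(conversion_from_mass(1, 1), 0)
  expect_equal(conversion_from_mass(0, 1), 1)
  expect_equal(conversion_from_mass(4, 5), 0.2)
  expect_error(conversion_from_mass(5.1, 5), "gain")
})

test_that("mass reconstruction maps state occupations to observed mass", {
  expect_equal(relative_mass(1, 0, 0, 0, 0.3, 0.5), 0)
  expect_equal(relative_mass(0, 0, 0, 1, 0.3, 0.5), 1)
  expect_equal(relative_mass(0, 1, 0, 0, 0.13, 0.48), 0.13)
  expect_equal(observed_mass(0, 1, -0.9), 1)
  expect_equal(observed_mass(1, 1, -0.9), 0.1)
  expect_equal(observed_mass(0.5, 1, -0.9), 0.55)
})

test_that("the ODE right-hand side obeys the balance identities", {
  pr <- make_ramp_hold(600, 600, 1, 1000) # isothermal 600 K
  m <- toy_three_step_model("product")
  # unseeded pristine state is a fixed point of the product convention
  d0 <- ode_rhs(c(1, 0, 0), 10, m, pr)
  expect_equal(d0, c(0, 0, 0, 0))
  # the four derivatives always sum to zero
  for (st in list(c(0.7, 0.2, 0.05), c(0.3, 0.3, 0.2), c(0.1, 0.1, 0.1))) {
    expect_equal(sum(ode_rhs(st, 10, m, pr)), 0, tolerance = 1e-15)
    expect_lte(ode_rhs(st, 10, m, pr)[1], 0) # A only decays
  }
  # hand substitution, product convention, M1 = N1 = 1, state (0.5, 0.5, 0)
  m2 <- consec_model(list(step_kinetics(1e5, 1e8, 1, 1),
                          step_kinetics(1e5, 0, 0.5, 2),
                          step_kinetics(1e5, 0, 0.5, 2)),
                     w1 = 1, w2 = 0, delta_m = -1, conversion = "product")
  k1 <- arrhenius_rate_constant(m2$steps[[1]], 600)
  expect_equal(ode_rhs(c(0.5, 0.5, 0), 10, m2, pr)[1], -k1 * 0.25)
})

test_that("the integrated single-step first-order limit matches 1 - exp(-kt)", {
  A <- 2.8e8; E <- 1e5; T_iso <- 500
  k <- A * exp(-E / (8.314 * T_iso))
  t_end <- 5 * log(2) / k
  m <- single_step_model(E, A, M = 0, N = 1)
  pr <- make_ramp_hold(T_iso, T_iso, 1, t_end)
  grid <- seq(1, t_end, length.out = 500)
  tr <- integrate_model(m, pr, grid)
  alpha <- 1 - tr$m_A
  expect_lt(max(abs(alpha - (1 - exp(-k * grid)))), 1e-6)
})

test_that("occupations are conserved and bounded across random models", {
  set.seed(1234)
  pr <- make_linear_ramp(C_to_K(30), C_to_K(550), rate_to_K_s(10))
  grid <- seq(1, program_duration(pr), length.out = 200)
  for (i in 1:25) {
    m <- random_model()
    tr <- integrate_model(m, pr, grid)
    expect_lt(max(abs(tr$m_A + tr$m_B + tr$m_C + tr$m_D - 1)), 1e-8)
    expect_true(all(tr$m_rel >= 0 & tr$m_rel <= 1 + 1e-9))
    # heating-only: source decays, final product accumulates, mass loss
    # progresses monotonically
    expect_true(all(diff(tr$m_A) <= 1e-7))
    expect_true(all(diff(tr$m_D) >= -1e-7))
    expect_true(all(diff(tr$m_rel) >= -1e-7))
  }
})

test_that("the adaptive solver agrees with an independent RK4 oracle", {
  # three-step toy in the product convention: every term is smooth on the
  # absolute scale, so the fixed-step oracle converges at dt = 0.01
  mc <- toy_three_step_model("product")
  pr <- make_ramp_hold(600, 600, 1, 100)
  steps <- lapply(mc$steps, function(s) list(E0 = s$E$E0, A = s$A,
                                             M = s$M, N = s$N))
  orc <- oracle_rk4(steps, function(t) 600, t_end = 100, dt = 0.01,
                    conversion = "product")
  grid <- orc[-1, "t"]
  tr <- integrate_model(mc, pr, grid)
  m_rel_oracle <- oracle_m_rel(orc[-1, , drop = FALSE], mc$w1, mc$w2)
  expect_lt(max(abs(tr$m_rel - m_rel_oracle)), 1e-6)

  # step-conversion convention checked on a single-step model, which has no
  # seed-scale quotient boundary layer (that layer is resolvable only by an
  # adaptive solver)
  ms <- single_step_model(1e5, 2.8e8, M = 1, N = 1.5)
  k_ref <- 2.8e8 * exp(-1e5 / (8.314 * 520))
  t_end <- 40 / k_ref
  prs <- make_ramp_hold(520, 520, 1, t_end)
  stepss <- list(list(E0 = 1e5, A = 2.8e8, M = 1, N = 1.5),
                 list(E0 = 1e5, A = 0, M = 0.5, N = 2),
                 list(E0 = 1e5, A = 0, M = 0.5, N = 2))
  orc2 <- oracle_rk4(stepss, function(t) 520, t_end = t_end, dt = t_end / 10000,
                     conversion = "step")
  grid2 <- orc2[-1, "t"]
  tr2 <- integrate_model(ms, prs, grid2)
  expect_lt(max(abs(tr2$m_rel - oracle_m_rel(orc2[-1, , drop = FALSE], 1, 0))),
            1e-6)
})

test_that("the plain-R and compiled right-hand sides integrate identically", {
  m <- toy_three_step_model()
  pr <- make_ramp_hold(600, 600, 1, 50)
  grid <- seq(1, 50, by = 1)
  a <- integrate_model(m, pr, grid, compiled = TRUE)
  b <- integrate_model(m, pr, grid, compiled = FALSE)
  expect_lt(max(abs(a$m_rel - b$m_rel)), 1e-8)
})

test_that("peak temperatures shift upward with heating rate", {
  m <- default_model("N2")
  Tp <- vapply(c(1, 5, 20), function(q) {
    pr <- make_linear_ramp(C_to_K(30), C_to_K(550), rate_to_K_s(q))
    grid <- seq(1, program_duration(pr), length.out = 2000)
    tr <- integrate_model(m, pr, grid)
    dm <- diff(tr$m_rel) / diff(tr$T_K)
    tr$T_K[which.max(dm)]
  }, numeric(1))
  expect_true(all(diff(Tp) > 0))
})

test_that("trajectories are insensitive to the start-up seed", {
  pr <- make_linear_ramp(C_to_K(30), C_to_K(550), rate_to_K_s(10))
  grid <- seq(1, program_duration(pr), length.out = 500)
  base <- default_model("N2")
  m1 <- consec_model(base$steps, base$w1, base$w2, base$delta_m,
                     seed_eps = 1e-8)
  m2 <- consec_model(base$steps, base$w1, base$w2, base$delta_m,
                     seed_eps = 5e-9)
  tr1 <- integrate_model(m1, pr, grid)
  tr2 <- integrate_model(m2, pr, grid)
  expect_lt(max(abs(tr1$m_rel - tr2$m_rel)), 1e-4)
})

test_that("integration warns when E(T) is clamped outside its window", {
  E <- activation_energy_poly(b = -20000, c = -1e6, T_min = 450, T_max = 650)
  m <- consec_model(list(step_kinetics(E, 1e10, 0.5, 1.5),
                         step_kinetics(180e3, 1e12, 0.5, 1.5),
                         step_kinetics(200e3, 1e13, 0.5, 1.5)),
                    w1 = 0.3, w2 = 0.3, delta_m = -0.9)
  pr <- make_linear_ramp(C_to_K(30), C_to_K(550), rate_to_K_s(10))
  expect_warning(integrate_model(m, pr, c(100, 200, 300)), "clamped")
})

test_that("model JSON serialisation round-trips bit-exactly", {
  tmp1 <- tempfile(fileext = ".json"); tmp2 <- tempfile(fileext = ".json")
  m <- default_model("air")
  write_model(m, tmp1)
  m2 <- read_model(tmp1)
  write_model(m2, tmp2)
  expect_identical(readLines(tmp1), readLines(tmp2))
  expect_equal(m2$w1, m$w1)
  expect_equal(m2$steps[[2]]$A, m$steps[[2]]$A)
  # temperature-dependent E variant
  mE <- consec_model(list(
    step_kinetics(activation_energy_poly(-2e4, -1e6, 450, 650), 1e10, 0.5, 1.5),
    step_kinetics(180e3, 1e12, 0.5, 1.5),
    step_kinetics(200e3, 1e13, 0.5, 1.5)),
    w1 = 0.3, w2 = 0.3, delta_m = -0.9)
  write_model(mE, tmp1)
  mE2 <- read_model(tmp1)
  write_model(mE2, tmp2)
  expect_identical(readLines(tmp1), readLines(tmp2))
  expect_equal(mE2$steps[[1]]$E$b, -2e4)
})
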