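make_ramp_curve <- function(T_C, m_pct, q = 10, meta = list()) {
  tga_curve(t = (T_C - T_C[1]) * 60 / q, T_C = T_C, m_pct = m_pct,
            meta = c(meta, list(q_plus_C_per_min = q)))
}

test_that("the local-regression derivative is exact for linear data", {
  T_C <- seq(100, 300, by = 0.5)
  cur <- make_ramp_curve(T_C, 100 - 0.001 * (T_C - 100))
  d <- mass_derivative(cur)
  expect_lt(max(abs(d$dm_dT + 0.001)), 1e-8)
  flat <- make_ramp_curve(T_C, rep(100, length(T_C)))
  expect_lt(max(abs(mass_derivative(flat)$dm_dT)), 1e-9)
})

test_that("derivative preconditions are enforced", {
  T_C <- seq(100, 103.6, by = 0.3)
  cur <- make_ramp_curve(T_C, 100 - 0.01 * (T_C - 100))
  expect_error(mass_derivative(cur), "span")
  bad <- tga_curve(1:20, c(seq(100, 109), seq(108, 99)), rep(100, 20))
  expect_error(mass_derivative(bad), "monotone")
})

test_that("the derivative minimum matches the known peak of a single step", {
  m <- single_step_model(150e3, 1e12, 0.3, 1.2)
  pr <- make_linear_ramp(C_to_K(30), C_to_K(550), rate_to_K_s(10))
  grid <- seq(1, program_duration(pr), by = 1)
  tr <- integrate_model(m, pr, grid)
  cur <- tga_curve(tr$t, K_to_C(tr$T_K), pmax(100 * tr$m, 1e-6),
                   meta = list(q_plus_C_per_min = 10))
  # brute-force reference from the dense noiseless forward model
  dmdT <- diff(tr$m_rel) / diff(tr$T_K)
  Tp_ref <- K_to_C(tr$T_K[which.max(dmdT)])
  d <- mass_derivative(cur)
  expect_lt(abs(d$T_C[which.min(d$dm_dT)] - Tp_ref), 0.5)
  pk <- find_step_peaks(d, n_steps = 1)
  expect_lt(abs(pk$Tp_C - Tp_ref), 0.5)
})

test_that("three synthetic steps are found at their true temperatures", {
  m <- default_model("N2")
  pr <- make_linear_ramp(C_to_K(30), C_to_K(550), rate_to_K_s(10))
  grid <- seq(1, program_duration(pr), by = 1)
  tr <- integrate_model(m, pr, grid)
  cur <- tga_curve(tr$t, K_to_C(tr$T_K), pmax(100 * tr$m, 1e-6))
  dmdT <- diff(tr$m_rel) / diff(tr$T_K)
  pk <- find_step_peaks(mass_derivative(cur))
  expect_equal(pk$step_index, 1:3)
  expect_true(!is.unsorted(pk$Tp_C, strictly = TRUE))
  # each within 1 C of the dense-model local maxima of the loss rate
  for (s in 1:3) {
    sel <- which(abs(K_to_C(tr$T_K[-1]) - pk$Tp_C[s]) < 15)
    expect_lt(abs(K_to_C(tr$T_K[sel][which.max(dmdT[sel])]) - pk$Tp_C[s]), 1)
  }
})

test_that("flat signals and missing peaks raise informative errors", {
  T_C <- seq(100, 300, by = 0.5)
  flat <- make_ramp_curve(T_C, rep(100, length(T_C)))
  expect_error(find_step_peaks(mass_derivative(flat)), "flat|peak")
  one_step <- make_ramp_curve(T_C, 100 - 50 * plogis((T_C - 200) / 10))
  expect_error(find_step_peaks(mass_derivative(one_step), n_steps = 3),
               "found only")
})

test_that("the linear Kissinger fit is exact on exact data", {
  E <- 150e3; const <- 25
  Tp_K <- seq(500, 560, by = 12)
  # construct q from the Kissinger relation itself
  q_K_s <- Tp_K^2 * exp(-E / (8.314 * Tp_K) + const)
  pts <- data.frame(q_plus_C_per_min = q_K_s * 60, Tp_K = Tp_K)
  fit <- kissinger_fit(pts)
  expect_equal(fit$E, 150e3, tolerance = 1e-10)
  expect_gt(fit$r_squared, 1 - 1e-12)
  expect_error(kissinger_fit(pts[1:2, ]), "3")
  expect_error(kissinger_fit(data.frame(q_plus_C_per_min = c(1, 2, 3),
                                        Tp_K = c(500, 500, 510))),
               "singular|duplicated")
})

test_that("Kissinger analysis of simulated single-step curves recovers E", {
  E <- 150e3
  m <- single_step_model(E, 1e12, 0.3, 1.2)
  rows <- lapply(c(0.5, 1, 2, 5, 10, 20), function(q) {
    pr <- make_linear_ramp(C_to_K(30), C_to_K(550), rate_to_K_s(q))
    grid <- seq(1, program_duration(pr), length.out = 4000)
    tr <- integrate_model(m, pr, grid)
    cur <- tga_curve(tr$t, K_to_C(tr$T_K), pmax(100 * tr$m, 1e-6),
                     meta = list(q_plus_C_per_min = q))
    pk <- find_step_peaks(mass_derivative(cur), n_steps = 1)
    data.frame(q_plus_C_per_min = q, Tp_K = C_to_K(pk$Tp_C))
  })
  pts <- do.call(rbind, rows)
  fit <- kissinger_fit(pts)
  expect_lt(abs(fit$E - E) / E, 0.03) # Kissinger is an approximation
})

test_that("heating-rate units only move the intercept, never E", {
  Tp_K <- c(500, 515, 528, 540, 552)
  q <- c(0.5, 1, 2, 5, 10)
  f1 <- kissinger_fit(data.frame(q_plus_C_per_min = q, Tp_K = Tp_K))
  # same rates expressed 60x larger (as if min-based values were per second)
  f2 <- kissinger_fit(data.frame(q_plus_C_per_min = 60 * q, Tp_K = Tp_K))
  expect_equal(f1$E, f2$E, tolerance = 1e-12)
  expect_equal(f2$intercept - f1$intercept, log(60), tolerance = 1e-9)
})

test_that("the quadratic Kissinger form reproduces a prescribed E(T)", {
  b <- -21000; cc <- -9e5
  Tp_K <- seq(480, 580, by = 20)
  x <- 1 / Tp_K
  y <- 3 + b * x + cc * x^2
  q_K_s <- exp(y) * Tp_K^2
  pts <- data.frame(q_plus_C_per_min = q_K_s * 60, Tp_K = Tp_K)
  qd <- kissinger_quadratic(pts)
  Tt <- seq(480, 580, by = 5)
  expect_equal(activation_energy_at(qd, Tt), -8.314 * (b + 2 * cc / Tt),
               tolerance = 1e-9)
  expect_error(activation_energy_at(qd, 470), "window")
  expect_equal(activation_energy_at(qd, 470, clamp = TRUE),
               activation_energy_at(qd, 480))
  # degenerate quadratic (c = 0) gives a constant E equal to the linear fit
  y_lin <- 3 + b * x
  pts_lin <- data.frame(q_plus_C_per_min = exp(y_lin) * Tp_K^2 * 60,
                        Tp_K = Tp_K)
  qd0 <- kissinger_quadratic(pts_lin)
  expect_equal(activation_energy_at(qd0, c(500, 560)),
               rep(-8.314 * b, 2), tolerance = 1e-6)
})

test_that("mode selection separates straight from curved Kissinger plots", {
  Tp_K <- seq(480, 580, by = 20)
  x <- 1 / Tp_K
  mk <- function(y) data.frame(q_plus_C_per_min = exp(y) * Tp_K^2 * 60,
                               Tp_K = Tp_K)
  expect_equal(select_E_mode(mk(3 - 20000 * x)), "linear")
  expect_equal(select_E_mode(mk(3 - 20000 * x - 3e6 * x^2)), "quadratic")
  # curvature that would imply negative E stays linear
  expect_equal(select_E_mode(mk(3 - 1000 * x + 1e6 * x^2)), "linear")
})

test_that("per-curve fixed E hand-off uses E(Tp) for curved steps", {
  st <- generate_study(study_design(q_list = c(0.5, 2, 5, 10, 20),
                                    atmosphere_models = list(N2 = default_model("N2"))),
                       noise_spec(seed = 3))
  ka <- kissinger_analysis(st$curves)
  fe <- fixed_E_for_curve(ka, "N2_q10")
  expect_length(fe, 3)
  expect_true(all(fe > 1e5 & fe < 3e5))
  # linear steps hand off the global E
  for (s in 1:3) {
    res <- ka$fits[[paste("N2", s, sep = ".")]]
    if (res$mode == "linear") expect_equal(fe[s], res$E)
  }
  expect_error(fixed_E_for_curve(ka, "nope"), "unknown")
})
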