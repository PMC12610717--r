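noiseless_curve <- function(atmosphere = "N2", q = 10) {
  m <- default_model(atmosphere)
  pr <- make_linear_ramp(C_to_K(30), C_to_K(550), rate_to_K_s(q))
  generate_curve(m, pr, sampling_interval = 1,
                 meta = list(sample_id = paste0(atmosphere, "_q", q),
                             atmosphere = atmosphere, q_plus_C_per_min = q))
}

truth_start <- function(model) {
  # round-trips 10^x exactly for the fixture's 3-decimal log10 A values
  list(log10_A = round(vapply(model$steps, function(s) log10(s$A), numeric(1)), 3),
       M = vapply(model$steps, `[[`, numeric(1), "M"),
       N = vapply(model$steps, `[[`, numeric(1), "N"),
       w1 = model$w1, w2 = model$w2)
}

test_that("rss is the plain sum of squared residuals", {
  expect_equal(rss(1:5, 1:5), 0)
  expect_equal(rss(rep(1, 10), rep(0.9, 10)), 0.1, tolerance = 1e-12)
  expect_equal(rss(3, 1), 4)
  expect_error(rss(1:3, 1:4), "equal length")
})

test_that("fit quality is the squared Pearson correlation", {
  expect_equal(fit_quality(1:10, 1:10), 1)
  expect_equal(fit_quality(c(1, 2, 3), rep(2, 3)), 0) # zero covariance
  obs <- c(0, 1, 2); calc <- c(0, 1, 1)
  # direct formula as oracle
  r_hand <- sum((obs - mean(obs)) * (calc - mean(calc))) /
    sqrt(sum((obs - mean(obs))^2) * sum((calc - mean(calc))^2))
  expect_equal(fit_quality(obs, calc), r_hand^2)
  expect_error(fit_quality(rep(1, 5), 1:5), "variance")
})

test_that("the truth is a stationary point of the noiseless fit", {
  cur <- noiseless_curve()
  m <- default_model("N2")
  # fitting on the curve's full grid makes the generator and the fit share
  # one forward computation, so the truth is an exact stationary point
  spec <- fit_spec(fixed_E = vapply(m$steps, function(s) s$E$E0, numeric(1)),
                   delta_m = m$delta_m, m_t0 = 1, max_fit_points = 1e9)
  f <- fit_curve(cur, spec, start = truth_start(m))
  expect_lt(f$rss, 1e-12)
  tr <- truth_start(m)
  expect_lt(max(abs(coef(f) - c(tr$log10_A, tr$M, tr$N, tr$w1, tr$w2))),
            1e-6)
  expect_equal(f$fit_quality, 1, tolerance = 1e-9)
})

test_that("fits are deterministic", {
  st <- generate_study(study_design(q_list = 10,
                                    atmosphere_models = list(N2 = default_model("N2"))),
                       noise_spec(seed = 21))
  cur <- st$curves[[1]]
  tru <- st$manifest[1, ]
  spec <- fit_spec(fixed_E = c(tru$E1, tru$E2, tru$E3))
  f1 <- fit_curve(cur, spec)
  f2 <- fit_curve(cur, spec)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$rss, f2$rss)
})

test_that("the final RSS never exceeds any multistart initial RSS", {
  st <- generate_study(study_design(q_list = 5,
                                    atmosphere_models = list(air = default_model("air"))),
                       noise_spec(seed = 33))
  tru <- st$manifest[1, ]
  f <- fit_curve(st$curves[[1]], fit_spec(fixed_E = c(tru$E1, tru$E2, tru$E3)))
  expect_true(all(f$rss <= f$diagnostics$rss_init + 1e-9))
  expect_equal(nrow(f$diagnostics), 9) # 3 x 3 exponent grid
})

test_that("closed-loop recovery on a noisy curve meets tolerance", {
  st <- generate_study(study_design(q_list = 2,
                                    atmosphere_models = list(N2 = default_model("N2"))),
                       noise_spec(seed = 42))
  cur <- st$curves[[1]]
  tru <- st$manifest[1, ]
  f <- fit_curve(cur, fit_spec(fixed_E = c(tru$E1, tru$E2, tru$E3)))
  p <- coef(f)
  expect_true(all(abs(p[1:3] - c(tru$log10_A1, tru$log10_A2, tru$log10_A3)) <= 0.3))
  M_t <- c(tru$M1, tru$M2, tru$M3); N_t <- c(tru$N1, tru$N2, tru$N3)
  expect_true(all(abs(p[4:6] - M_t) <= pmax(0.15, 0.25 * M_t)))
  expect_true(all(abs(p[7:9] - N_t) <= pmax(0.15, 0.25 * N_t)))
  expect_lte(abs(p[["w1"]] - tru$w1), 0.03)
  expect_lte(abs(p[["w2"]] - tru$w2), 0.03)
})

test_that("a curve truncated before the plateau cannot fix delta_m from data", {
  m <- default_model("N2")
  pr <- make_linear_ramp(C_to_K(30), C_to_K(330), rate_to_K_s(10))
  cur <- generate_curve(m, pr, sampling_interval = 1)
  E <- vapply(m$steps, function(s) s$E$E0, numeric(1))
  expect_error(fit_curve(cur, fit_spec(fixed_E = E)), "plateau")
})

test_that("displacing the fixed E is compensated by the pre-exponent", {
  cur <- noiseless_curve()
  m <- default_model("N2")
  E0 <- vapply(m$steps, function(s) s$E$E0, numeric(1))
  f_true <- fit_curve(cur, fit_spec(fixed_E = E0, delta_m = m$delta_m),
                      start = truth_start(m))
  f_disp <- fit_curve(cur, fit_spec(fixed_E = 1.1 * E0, delta_m = m$delta_m),
                      start = truth_start(m))
  dlA <- coef(f_disp)[1:3] - coef(f_true)[1:3]
  expect_true(all(dlA > 0)) # higher E demands higher A: compensation
  # and the compensated fit still describes the curve well
  expect_gt(f_disp$fit_quality, 0.999)
})

test_that("the trend table maps weights to step representations", {
  st <- generate_study(study_design(q_list = c(2, 10)), noise_spec(seed = 9))
  fits <- lapply(names(st$curves), function(id) {
    tru <- st$manifest[st$manifest$sample_id == id, ]
    fit_curve(st$curves[[id]], fit_spec(fixed_E = c(tru$E1, tru$E2, tru$E3)))
  })
  tt <- build_trend_table(fits)
  expect_equal(nrow(tt), 4)
  expect_equal(tt$I1 + tt$I2 + tt$I3, rep(100, 4), tolerance = 1e-9)
  # sorted by atmosphere then heating rate
  expect_equal(order(tt$atmosphere, tt$q_plus_C_per_min), 1:4)
  expect_true(all(tt$fit_quality > 0.999))
  # single-fit mapping check
  one <- build_trend_table(fits[1])
  expect_equal(one$I1, 100 * coef(fits[[1]])[["w1"]])
})
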