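# Independent fixed-step RK4 integrator for the consecutive scheme, written
# directly from the rate equations (not via the package's ODE right-hand
# side), used as a brute-force oracle for the adaptive solver.

oracle_sb <- function(a, M, N) {
  a <- min(max(a, 0), 1)
  a^M * (1 - a)^N
}

oracle_rhs <- function(y, T_K, steps, conversion = "step") {
  mA <- y[1]; mB <- y[2]; mC <- y[3]
  mD <- 1 - mA - mB - mC
  k <- vapply(steps, function(s) s$A * exp(-s$E0 / (8.314 * T_K)), numeric(1))
  if (conversion == "step") {
    a <- c(1 - mA, (mC + mD) / (1 - mA + 1e-9), mD / (mC + mD + 1e-9))
  } else {
    a <- c(mB, mC, mD)
  }
  g <- pmin(pmax(c(mA, mB, mC) / 1e-6, 0), 1)
  g <- g^2 * (3 - 2 * g)
  r <- vapply(1:3, function(j)
    g[j] * k[j] * oracle_sb(a[j], steps[[j]]$M, steps[[j]]$N), numeric(1))
  c(-r[1], r[1] - r[2], r[2] - r[3])
}

# steps: list of list(E0, A, M, N); temp_fn: T(t) in kelvin
oracle_rk4 <- function(steps, temp_fn, t_end, dt, seed_eps = 1e-8,
                       conversion = "step") {
  n <- ceiling(t_end / dt)
  y <- c(1 - 3 * seed_eps, seed_eps, seed_eps)
  out <- matrix(NA_real_, n + 1, 4)
  out[1, ] <- c(0, y)
  for (i in seq_len(n)) {
    t0 <- (i - 1) * dt
    k1 <- oracle_rhs(y, temp_fn(t0), steps, conversion)
    k2 <- oracle_rhs(y + dt / 2 * k1, temp_fn(t0 + dt / 2), steps, conversion)
    k3 <- oracle_rhs(y + dt / 2 * k2, temp_fn(t0 + dt / 2), steps, conversion)
    k4 <- oracle_rhs(y + dt * k3, temp_fn(t0 + dt), steps, conversion)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[i + 1, ] <- c(t0 + dt, y)
  }
  colnames(out) <- c("t", "mA", "mB", "mC")
  out
}

oracle_m_rel <- function(states, w1, w2) {
  mD <- 1 - states[, "mA"] - states[, "mB"] - states[, "mC"]
  w1 * (1 - states[, "mA"]) + w2 * (states[, "mC"] + mD) +
    (1 - w1 - w2) * mD
}

# convenience builders ------------------------------------------------------

# single active step; steps 2 and 3 switched off (A = 0)
single_step_model <- function(E, A, M, N, seed_eps = 1e-8,
                              conversion = "step") {
  consec_model(list(step_kinetics(E, A, M, N),
                    step_kinetics(1e5, 0, 0.5, 2),
                    step_kinetics(1e5, 0, 0.5, 2)),
               w1 = 1, w2 = 0, delta_m = -1, seed_eps = seed_eps,
               conversion = conversion)
}

# exponents M >= 1 keep the rate function smooth at the seeded start, so a
# fixed-step oracle converges cleanly
toy_three_step_model <- function(conversion = "step") {
  consec_model(list(step_kinetics(80e3, 4.6e6, 1.0, 1.2),
                    step_kinetics(95e3, 1.3e8, 1.2, 1.5),
                    step_kinetics(110e3, 3.8e9, 1.0, 2.0)),
               w1 = 0.2, w2 = 0.45, delta_m = -0.85,
               conversion = conversion)
}

# random model draw used by property-style tests
random_model <- function() {
  E <- sort(runif(3, 80e3, 250e3))
  lA <- sort(runif(3, 6, 16))
  steps <- lapply(1:3, function(j)
    step_kinetics(E[j], 10^lA[j], runif(1, 0, 1.5), runif(1, 0.5, 6)))
  w1 <- runif(1, 0.05, 0.5)
  w2 <- runif(1, 0.05, 1 - w1 - 0.05)
  consec_model(steps, w1 = w1, w2 = w2, delta_m = -runif(1, 0.5, 1))
}
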