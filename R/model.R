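#' Universal gas constant
#'
#' J mol-1 K-1, as used in all Arrhenius terms in this package.
#' @export
R_gas <- 8.314

#' Activation energy specification
#'
#' Either a constant activation energy (J/mol) or a temperature-dependent one
#' derived from a quadratic Kissinger fit, \eqn{E(T) = -R (b + 2 c / T)},
#' valid over a stated kelvin window (see [kissinger_quadratic()]). Outside
#' the window `E_at()` clamps to the window-edge value; integration routines
#' warn when clamping is active.
#'
#' @param E0 constant activation energy, J/mol (>= 0).
#' @param b,c coefficients of the quadratic Kissinger fit in the coordinates
#'   y = ln(q/Tp^2) versus x = 1/Tp.
#' @param T_min,T_max validity window, kelvin.
#' @return an `activation_energy` object.
#' @examples
#' activation_energy(150e3)
#' activation_energy_poly(-20, -9000, 450, 650)
#' @export
activation_energy <- function(E0) {
  if (!is.finite(E0) || E0 < 0) stop("E0 must be finite and >= 0", call. = FALSE)
  structure(list(mode = "constant", E0 = E0), class = "activation_energy")
}

#' @rdname activation_energy
#' @export
activation_energy_poly <- function(b, c, T_min, T_max) {
  stopifnot(is.finite(b), is.finite(c), T_min > 0, T_max > T_min)
  obj <- structure(list(mode = "temperature_dependent", b = b, c = c,
                        T_min = T_min, T_max = T_max),
                   class = "activation_energy")
  Tt <- seq(T_min, T_max, length.out = 64)
  if (any(!is.finite(E_at(obj, Tt))) || any(E_at(obj, Tt) <= 0))
    stop("E(T) must be finite and positive over the validity window",
         call. = FALSE)
  obj
}

as_activation_energy <- function(E) {
  if (inherits(E, "activation_energy")) E else activation_energy(E)
}

#' Evaluate an activation energy at a temperature
#'
#' @param E an `activation_energy` (a plain number is taken as constant J/mol).
#' @param T_K temperature(s), kelvin.
#' @param clamp clamp temperature-dependent E to its validity window (default);
#'   `clamp = FALSE` raises an error outside the window.
#' @return activation energy value(s), J/mol.
#' @export
E_at <- function(E, T_K, clamp = TRUE) {
  E <- as_activation_energy(E)
  if (E$mode == "constant") return(rep(E$E0, length(T_K)))
  if (!clamp && (any(T_K < E$T_min) || any(T_K > E$T_max)))
    stop("temperature outside the E(T) validity window", call. = FALSE)
  Tc <- pmin(pmax(T_K, E$T_min), E$T_max)
  -R_gas * (E$b + 2 * E$c / Tc)
}

#' Kinetics of one decomposition step
#'
#' Arrhenius parameters plus the two exponents of the autocatalytic
#' Sestak-Berggren function \eqn{f(\alpha) = \alpha^M (1-\alpha)^N}.
#' `A = 0` is allowed and denotes an inert (switched-off) step, used to
#' express single-step reductions of the consecutive scheme.
#'
#' @param E activation energy, J/mol, or an [activation_energy()] object.
#' @param A pre-exponential constant, 1/s (>= 0).
#' @param M first (accelerating) exponent, >= 0.
#' @param N second (decelerating) exponent, > 0.
#' @return a `step_kinetics` object.
#' @export
step_kinetics <- function(E, A, M, N) {
  E <- as_activation_energy(E)
  if (!is.finite(A) || A < 0) stop("A must be finite and >= 0", call. = FALSE)
  if (!is.finite(M) || M < 0) stop("M must be finite and >= 0", call. = FALSE)
  if (!is.finite(N) || N <= 0) stop("N must be finite and > 0", call. = FALSE)
  structure(list(E = E, A = A, M = M, N = N), class = "step_kinetics")
}

#' Sestak-Berggren autocatalytic model function
#'
#' \eqn{f(\alpha) = \alpha^M (1-\alpha)^N}. With `M = 0` the function reduces
#' to the reaction-order form \eqn{(1-\alpha)^N}; for `M > 0` it vanishes at
#' both endpoints, giving the accelerating-then-decelerating shape typical of
#' autocatalytic solid-state decompositions.
#'
#' @param alpha degree of conversion, in `[0, 1]`.
#' @param M,N kinetic exponents (`M >= 0`, `N > 0`).
#' @return f(alpha), dimensionless.
#' @examples
#' sestak_berggren(0.5, 1, 1) # 0.25
#' @export
sestak_berggren <- function(alpha, M, N) {
  if (any(!is.finite(alpha)) || any(alpha < 0) || any(alpha > 1))
    stop("alpha must lie in [0, 1]", call. = FALSE)
  stopifnot(M >= 0, N > 0)
  alpha^M * (1 - alpha)^N
}

#' Arrhenius rate constant of a step
#'
#' \eqn{k(T) = A \exp(-E(T)/(R T))}.
#'
#' @param step a [step_kinetics()] object.
#' @param T_K temperature(s), kelvin (> 0). For temperature-dependent E the
#'   temperature must lie inside the validity window unless `clamp = TRUE`.
#' @param clamp clamp E(T) at the window edges instead of erroring.
#' @return rate constant(s), 1/s.
#' @export
arrhenius_rate_constant <- function(step, T_K, clamp = FALSE) {
  stopifnot(inherits(step, "step_kinetics"))
  if (any(!is.finite(T_K)) || any(T_K <= 0))
    stop("temperature must be positive kelvin", call. = FALSE)
  step$A * exp(-E_at(step$E, T_K, clamp = clamp) / (R_gas * T_K))
}

#' Degree of conversion from mass
#'
#' \eqn{\alpha = (m_0 - m)/m_0}, scaled to `[0, 1]`. Mass gain (m > m0 beyond
#' a 1e-6 tolerance) is not modelled and raises an error.
#'
#' @param m actual sample mass (any consistent unit).
#' @param m0 original sample mass (> 0).
#' @return conversion(s) in `[0, 1]`.
#' @export
conversion_from_mass <- function(m, m0) {
  stopifnot(m0 > 0)
  if (any(m > m0 * (1 + 1e-6)) || any(m < 0))
    stop("mass must lie in [0, m0]; mass gain is not modelled", call. = FALSE)
  pmin(pmax((m0 - m) / m0, 0), 1)
}

#' Consecutive three-step decomposition model
#'
#' The reaction scheme A -> B -> C -> D in which each transition is governed
#' by Arrhenius kinetics with a Sestak-Berggren rate function. The observable
#' mass is reconstructed from the state occupations via
#' \eqn{m_{rel} = w_1 (1 - m_A) + w_2 (m_C + m_D) + (1 - w_1 - w_2) m_D}
#' and \eqn{m = m_{t=0} + \Delta m \, m_{rel}}.
#'
#' Two conventions are provided for the conversion variable fed to each
#' step's rate function. The default `"step"` convention uses per-step
#' conversions (\eqn{\alpha_1 = 1 - m_A},
#' \eqn{\alpha_2 = (m_C + m_D)/(1 - m_A)},
#' \eqn{\alpha_3 = m_D/(m_C + m_D)}); each rate then vanishes automatically
#' both before its step has started and once its source species is exhausted,
#' which keeps the occupations in `[0, 1]` and lets well-separated steps
#' produce distinct derivative peaks. The `"product"` convention takes the
#' raw product-species amounts (step 1 uses m_B, step 2 m_C, step 3 m_D) as
#' the conversion variables. In either convention the pristine state
#' (1, 0, 0, 0) is a fixed point, so the integrator seeds every product
#' species with `seed_eps`; and every rate carries a smooth
#' source-availability gate (a smoothstep over `[0, 1e-6]`). In the product
#' convention the gate is what stops a step whose source has run out; in the
#' step convention it regularises the supply-limited regime, where the
#' decelerating factor with `N < 1` is otherwise not Lipschitz in the source
#' species. The gate only acts below one ppm of source material.
#'
#' @param steps list of exactly three [step_kinetics()] objects.
#' @param w1,w2 mass-loss weights of steps 1 and 2 (`w1, w2 >= 0`,
#'   `w1 + w2 <= 1`); step 3 carries `1 - w1 - w2`.
#' @param delta_m total relative mass change (signed; negative for loss),
#'   fraction of initial mass, `|delta_m| <= 1`.
#' @param m_t0 initial relative mass (1 for normalised data).
#' @param seed_eps start-up seed placed in m_B and m_C (0 < seed_eps <= 1e-4).
#' @param conversion `"step"` (per-step conversions, default) or
#'   `"product"` (literal product-species amounts with source gating).
#' @return a `consec_model` object.
#' @examples
#' m <- consec_model(
#'   list(step_kinetics(140e3, 1e10, 0.5, 2),
#'        step_kinetics(160e3, 1e11, 0.5, 2),
#'        step_kinetics(180e3, 1e12, 0.5, 2)),
#'   w1 = 0.13, w2 = 0.48, delta_m = -0.91)
#' @export
consec_model <- function(steps, w1, w2, delta_m, m_t0 = 1, seed_eps = 1e-8,
                         conversion = c("step", "product")) {
  conversion <- match.arg(conversion)
  if (length(steps) != 3L || !all(vapply(steps, inherits, TRUE, "step_kinetics")))
    stop("steps must be a list of exactly three step_kinetics objects",
         call. = FALSE)
  stopifnot(w1 >= 0, w2 >= 0, w1 + w2 <= 1 + 1e-12,
            abs(delta_m) <= 1, m_t0 > 0,
            seed_eps > 0, seed_eps <= 1e-4)
  structure(list(steps = steps, w1 = w1, w2 = w2, delta_m = delta_m,
                 m_t0 = m_t0, seed_eps = seed_eps, conversion = conversion),
            class = "consec_model")
}

#' @export
print.consec_model <- function(x, ...) {
  cat("Consecutive three-step decomposition model (A -> B -> C -> D)\n")
  for (i in 1:3) {
    s <- x$steps[[i]]
    Etxt <- if (s$E$mode == "constant")
      sprintf("E = %.1f kJ/mol", s$E$E0 / 1000)
    else
      sprintf("E(T) over [%.0f, %.0f] K", s$E$T_min, s$E$T_max)
    cat(sprintf("  step %d: %s, log10(A/s^-1) = %.3f, M = %.3f, N = %.3f\n",
                i, Etxt, log10(max(s$A, .Machine$double.xmin)), s$M, s$N))
  }
  cat(sprintf("  w1 = %.4f, w2 = %.4f, delta_m = %.4f, m(t=0) = %g\n",
              x$w1, x$w2, x$delta_m, x$m_t0))
  invisible(x)
}

#' Relative mass from state occupations
#'
#' @param m_A,m_B,m_C,m_D state occupations (each in `[0,1]`, summing to 1).
#' @param w1,w2 step weights.
#' @return relative (normalised) mass-loss progress in `[0, 1]`: 0 for intact
#'   material, 1 at complete decomposition.
#' @export
relative_mass <- function(m_A, m_B, m_C, m_D, w1, w2) {
  w1 * (1 - m_A) + w2 * (m_C + m_D) + (1 - w1 - w2) * m_D
}

#' Observed mass from relative mass-loss progress
#'
#' \eqn{m = m_{t=0} + \Delta m \, m_{rel}}; with normalised data and
#' `delta_m = -0.9`, full conversion gives m = 0.10.
#'
#' @param m_rel relative mass-loss progress in `[0, 1]`.
#' @param m_t0 initial relative mass.
#' @param delta_m total relative mass change (signed).
#' @return observed relative mass.
#' @export
observed_mass <- function(m_rel, m_t0, delta_m) m_t0 + delta_m * m_rel

# Kinetic-parameter block of the compiled parameter vector.
step_parms <- function(step) {
  E <- step$E
  if (E$mode == "constant")
    c(0, E$E0, 0, 0, 0, step$A, step$M, step$N)
  else
    c(1, E$b, E$c, E$T_min, E$T_max, step$A, step$M, step$N)
}

model_parms <- function(model, program) {
  c(program_parms(program),
    unlist(lapply(model$steps, step_parms)),
    if (model$conversion == "step") 1 else 0)
}

#' ODE right-hand side of the consecutive scheme
#'
#' The kinetic-plus-balance equations: with rates
#' \eqn{r_x = A_x \exp(-E_x/RT) f_x(\alpha_x)},
#' \eqn{dm_A/dt = -r_1}, \eqn{dm_B/dt = r_1 - r_2},
#' \eqn{dm_C/dt = r_2 - r_3}, and \eqn{dm_D/dt = r_3} (m_D is recovered
#' algebraically as \eqn{1 - m_A - m_B - m_C}, so mass conservation holds
#' exactly). In the default `"product"` convention the conversion variables
#' are \eqn{\alpha_1 = m_B}, \eqn{\alpha_2 = m_C}, \eqn{\alpha_3 = m_D}.
#' Exposed mainly for inspection and testing; [integrate_model()] uses a
#' compiled equivalent.
#'
#' @param state numeric vector `c(m_A, m_B, m_C)`.
#' @param t time, seconds.
#' @param model a [consec_model()].
#' @param program a `heating_program`.
#' @return numeric vector `c(dm_A/dt, dm_B/dt, dm_C/dt, dm_D/dt)`, 1/s.
#' @export
ode_rhs <- function(state, t, model, program) {
  if (any(!is.finite(state))) stop("non-finite state", call. = FALSE)
  T_K <- temperature_at(program, t)
  m_A <- min(max(state[1], 0), 1)
  m_B <- min(max(state[2], 0), 1)
  m_C <- min(max(state[3], 0), 1)
  m_D <- max(1 - m_A - m_B - m_C, 0)
  if (model$conversion == "product") {
    a <- c(m_B, m_C, m_D)
  } else {
    a <- c(1 - m_A,
           (m_C + m_D) / (1 - m_A + 1e-9),
           m_D / (m_C + m_D + 1e-9))
  }
  a <- pmin(pmax(a, 0), 1)
  r <- vapply(1:3, function(j) {
    s <- model$steps[[j]]
    arrhenius_rate_constant(s, T_K, clamp = TRUE) * sestak_berggren(a[j], s$M, s$N)
  }, numeric(1))
  # every rate is gated on its source species (see consec_model details)
  gate <- function(m_src) {
    g <- pmin(pmax(m_src / 1e-6, 0), 1)
    g^2 * (3 - 2 * g) # C1 smoothstep
  }
  r <- r * gate(c(m_A, m_B, m_C))
  c(-r[1], r[1] - r[2], r[2] - r[3], r[3])
}

#' Integrate the consecutive model under a heating program
#'
#' Solves the three-state ODE system with a stiff-capable adaptive solver
#' (deSolve's `lsoda`, compiled right-hand side) and reconstructs the
#' relative and observed mass at the requested output times. The initial
#' condition seeds the product species: m_B = m_C = `seed_eps`,
#' m_A = 1 - 2 `seed_eps`, m_D = 0.
#'
#' @param model a [consec_model()].
#' @param program a `heating_program` covering all of `output_grid`.
#' @param output_grid strictly increasing times, seconds, within the program.
#' @param rtol,atol solver tolerances. The defaults resolve the steep
#'   autocatalytic onsets over rate constants spanning many decades.
#' @param compiled use the compiled right-hand side (default); `FALSE` uses
#'   the plain-R [ode_rhs()] (slow; for checking).
#' @return a `state_trajectory`: data frame with columns `t`, `T_K`, `m_A`,
#'   `m_B`, `m_C`, `m_D`, `m_rel`, `m`.
#' @export
integrate_model <- function(model, program, output_grid,
                            rtol = 1e-8, atol = 1e-10, compiled = TRUE) {
  stopifnot(inherits(model, "consec_model"), inherits(program, "heating_program"))
  if (any(diff(output_grid) <= 0))
    stop("output_grid must be strictly increasing", call. = FALSE)
  if (output_grid[1] < 0 ||
      output_grid[length(output_grid)] > program$total_duration + 1e-9)
    stop("output_grid must lie within the program duration", call. = FALSE)

  warn_if_clamped(model, program)

  eps <- model$seed_eps
  # each step's rate function is autocatalytic in its own product species, so
  # every product (B, C and D) carries a small seed; D's seed is implied by
  # the algebraic closure m_D = 1 - m_A - m_B - m_C
  y0 <- c(1 - 3 * eps, eps, eps)
  times <- output_grid
  prepend <- times[1] > 0
  if (prepend) times <- c(0, times)

  dur <- program$total_duration
  solve_once <- function(rtol, atol, maxsteps) {
    if (compiled) {
      deSolve::lsoda(y0, times, func = "derivs_consec",
                     parms = model_parms(model, program),
                     dllname = "tgakin", initfunc = "initmod_consec",
                     rtol = rtol, atol = atol, maxsteps = maxsteps)
    } else {
      deSolve::lsoda(y0, times,
                     func = function(t, y, p) {
                       # the solver may probe marginally outside the program
                       t <- min(max(t, 0), dur)
                       list(ode_rhs(y, t, model, program)[1:3])
                     },
                     parms = NULL, rtol = rtol, atol = atol,
                     maxsteps = maxsteps)
    }
  }
  sol <- suppressWarnings(solve_once(rtol, atol, 50000))
  if (attr(sol, "istate")[1] < 0) {
    # pathologically stiff parameter draws: allow more work, then back off
    # the tolerances (conservation is enforced algebraically either way)
    sol <- suppressWarnings(solve_once(rtol, atol, 1000000))
    if (attr(sol, "istate")[1] < 0)
      sol <- suppressWarnings(solve_once(max(rtol, 1e-6), max(atol, 1e-8),
                                         1000000))
  }
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed (istate = ", attr(sol, "istate")[1], ")",
         call. = FALSE)
  if (prepend) sol <- sol[-1, , drop = FALSE]

  m_A <- pmin(pmax(sol[, 2], 0), 1)
  m_B <- pmin(pmax(sol[, 3], 0), 1)
  m_C <- pmin(pmax(sol[, 4], 0), 1)
  m_D <- pmin(pmax(1 - m_A - m_B - m_C, 0), 1)
  m_rel <- relative_mass(m_A, m_B, m_C, m_D, model$w1, model$w2)
  out <- data.frame(t = output_grid,
                    T_K = temperature_at(program, output_grid),
                    m_A = m_A, m_B = m_B, m_C = m_C, m_D = m_D,
                    m_rel = m_rel,
                    m = observed_mass(m_rel, model$m_t0, model$delta_m))
  class(out) <- c("state_trajectory", "data.frame")
  out
}

warn_if_clamped <- function(model, program) {
  T_range <- range(vapply(program$segments, function(s) c(s$T_start, s$T_end),
                          numeric(2)))
  for (j in 1:3) {
    E <- model$steps[[j]]$E
    if (E$mode == "temperature_dependent" &&
        (T_range[1] < E$T_min - 1e-9 || T_range[2] > E$T_max + 1e-9))
      warning(sprintf(
        "step %d: program temperatures extend outside the E(T) validity window [%.1f, %.1f] K; E clamped at the window edges",
        j, E$T_min, E$T_max), call. = FALSE)
  }
}

#' Serialise / read a consecutive model as JSON
#'
#' The document stores per-step activation energy (constant `E_kJ_mol` or
#' quadratic-coefficient block `E_poly`), `log10_A_per_s`, `M`, `N`, plus the
#' weights, total mass change, initial mass, seed and conversion convention.
#' Values are written with 17 significant digits so that
#' write -> read -> write is bit-exact.
#'
#' @param model a [consec_model()].
#' @param path file path.
#' @return `read_model` returns a `consec_model`; `write_model` returns
#'   `path` invisibly.
#' @export
write_model <- function(model, path) {
  steps <- lapply(model$steps, function(s) {
    E <- s$E
    base <- list(log10_A_per_s = log10(max(s$A, .Machine$double.xmin)),
                 M = s$M, N = s$N)
    if (E$mode == "constant")
      c(list(E_kJ_mol = E$E0 / 1000), base)
    else
      c(list(E_poly = list(b = E$b, c = E$c,
                           T_min_C = K_to_C(E$T_min),
                           T_max_C = K_to_C(E$T_max))), base)
  })
  doc <- list(steps = steps, w1 = model$w1, w2 = model$w2,
              delta_m = model$delta_m, m_t0 = model$m_t0,
              seed_eps = model$seed_eps, conversion = model$conversion)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                              pretty = TRUE), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  steps <- lapply(doc$steps, function(s) {
    E <- if (!is.null(s$E_kJ_mol)) {
      activation_energy(s$E_kJ_mol * 1000)
    } else {
      p <- s$E_poly
      activation_energy_poly(p$b, p$c, C_to_K(p$T_min_C), C_to_K(p$T_max_C))
    }
    step_kinetics(E, 10^s$log10_A_per_s, s$M, s$N)
  })
  consec_model(steps, w1 = doc$w1, w2 = doc$w2, delta_m = doc$delta_m,
               m_t0 = doc$m_t0, seed_eps = doc$seed_eps,
               conversion = if (is.null(doc$conversion)) "product" else doc$conversion)
}
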