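#' Residual sum of squares
#'
#' \eqn{RSS = \sum_k (Y_{exp,k} - Y_{cal,k})^2}; the objective minimised by
#' the per-curve fits.
#'
#' @param observed,calculated numeric series of equal length (>= 1).
#' @return a single non-negative number; zero iff the series are identical.
#' @export
rss <- function(observed, calculated) {
  if (length(observed) != length(calculated) || length(observed) < 1)
    stop("observed and calculated must have equal length >= 1", call. = FALSE)
  sum((observed - calculated)^2)
}

#' Fit-quality statistic
#'
#' Squared Pearson correlation between the observed and calculated mass
#' series, in `[0, 1]`. A calculated series with zero variance has zero
#' covariance with the data and scores 0 by convention.
#'
#' @param observed,calculated numeric series of equal length (>= 3).
#' @return squared correlation coefficient.
#' @export
fit_quality <- function(observed, calculated) {
  if (length(observed) != length(calculated) || length(observed) < 3)
    stop("need >= 3 paired points", call. = FALSE)
  if (sd(observed) == 0)
    stop("observed series has zero variance: quality undefined", call. = FALSE)
  if (sd(calculated) == 0) return(0)
  cor(observed, calculated)^2
}

#' Specification of a single-curve fit
#'
#' Controls the per-curve nonlinear least-squares fit of the consecutive
#' model with activation energies held fixed (the sc-MKA scheme): bounds,
#' the multistart grid over the kinetic exponents, the treatment of the
#' total mass change, and optimizer/integrator tolerances.
#'
#' @param fixed_E three per-step activation energies, J/mol (typically from
#'   [fixed_E_for_curve()]; for temperature-dependent steps the per-curve
#'   value E(Tp)).
#' @param delta_m `"fixed_from_data"` (default: from the final plateau, mean
#'   of the last 2 % of points; requires the curve to reach a plateau),
#'   `"free"` (optimised), or a number (fixed at that value, fraction of
#'   initial mass, negative for loss).
#' @param multistart_M,multistart_N initial-guess grids for the exponents;
#'   their Cartesian product defines the multistart set (default 3 x 3).
#' @param bounds named list of `c(lower, upper)` for `log10_A`, `M`, `N`,
#'   `w` (also used for per-parameter initialisation clipping).
#' @param coarse_maxit iterations allotted to each multistart probe before
#'   the best start is polished.
#' @param probe_top number of multistart points actually probed with the
#'   optimizer, chosen as those with the lowest initial RSS (all starts are
#'   always evaluated at their initial point).
#' @param maxit iteration cap for the polishing run.
#' @param ftol,ptol Levenberg-Marquardt convergence tolerances.
#' @param max_fit_points fits are evaluated on the curve's own grid thinned
#'   to at most this many points.
#' @param rtol,atol forward-model integration tolerances.
#' @param plateau_tol maximum |dm/dT| (percent per degree) over the last 5 %
#'   of points for the curve to count as fully decomposed.
#' @param m_t0 initial relative mass; `NULL` (default) estimates it from the
#'   first 1 % of points.
#' @param conversion conversion convention of the fitted model.
#' @return a `fit_spec` object.
#' @export
fit_spec <- function(fixed_E,
                     delta_m = "fixed_from_data",
                     multistart_M = c(0.1, 0.5, 1.0),
                     multistart_N = c(0.5, 1.5, 4),
                     bounds = list(log10_A = c(2, 20), M = c(0, 3),
                                   N = c(0.05, 12), w = c(0, 1)),
                     coarse_maxit = 12, probe_top = 4, maxit = 200,
                     ftol = 1e-10, ptol = 1e-8,
                     max_fit_points = 800,
                     rtol = 1e-8, atol = 1e-10,
                     plateau_tol = 0.02, m_t0 = NULL,
                     conversion = c("step", "product")) {
  stopifnot(length(fixed_E) == 3, all(is.finite(fixed_E)), all(fixed_E > 0))
  if (is.character(delta_m)) delta_m <- match.arg(delta_m, c("fixed_from_data", "free"))
  structure(list(fixed_E = fixed_E, delta_m = delta_m,
                 multistart_M = multistart_M, multistart_N = multistart_N,
                 bounds = bounds, coarse_maxit = coarse_maxit,
                 probe_top = probe_top, maxit = maxit,
                 ftol = ftol, ptol = ptol, max_fit_points = max_fit_points,
                 rtol = rtol, atol = atol, plateau_tol = plateau_tol,
                 m_t0 = m_t0, conversion = match.arg(conversion)),
            class = "fit_spec")
}

# linear-ramp program through a measured curve's endpoints
curve_program <- function(curve) {
  n <- length(curve$t)
  rate <- (curve$T_C[n] - curve$T_C[1]) / (curve$t[n] - curve$t[1])
  if (rate <= 0) stop("curve is not a heating ramp", call. = FALSE)
  make_linear_ramp(C_to_K(curve$T_C[1]), C_to_K(curve$T_C[n]), rate)
}

clip <- function(x, b) pmin(pmax(x, b[1] + 1e-9), b[2] - 1e-9)

# initial log10_A per step by matching the observed peak loss rate:
# k(Tp) * f(0.5) ~ peak step-conversion rate
init_log10A <- function(curve, peaks, fixed_E, M0, N0, w_init, delta_m_frac,
                        bounds) {
  q_K_s <- (max(curve$T_C) - min(curve$T_C)) /
    (max(curve$t) - min(curve$t))
  w3 <- max(1 - w_init[1] - w_init[2], 1e-3)
  wts <- c(max(w_init[1], 1e-3), max(w_init[2], 1e-3), w3)
  vapply(1:3, function(s) {
    Tp <- C_to_K(peaks$Tp_C[s])
    # peak dm/dT is in % per K; convert to step conversion per second
    rate <- abs(peaks$peak_dm_dT[s]) * q_K_s / (100 * abs(delta_m_frac) * wts[s])
    f05 <- sestak_berggren(0.5, M0, N0)
    A <- rate / (exp(-fixed_E[s] / (R_gas * Tp)) * f05)
    clip(log10(max(A, 1e-300)), bounds$log10_A)
  }, numeric(1))
}

# step weights from the mass level at the inter-peak valleys
init_weights <- function(curve, peaks, m0_pct, delta_m_frac) {
  total <- 100 * abs(delta_m_frac)
  lev <- vapply(1:2, function(s) {
    sel <- curve$T_C > peaks$Tp_C[s] & curve$T_C < peaks$Tp_C[s + 1]
    if (!any(sel)) return(NA_real_)
    d <- abs(diff(curve$m_pct[sel]) / diff(curve$T_C[sel]))
    mean(curve$m_pct[sel][which(d < stats::quantile(d, 0.1)) + 1L], na.rm = TRUE)
  }, numeric(1))
  if (any(!is.finite(lev))) return(c(0.2, 0.4))
  w1 <- (m0_pct - lev[1]) / total
  w2 <- (lev[1] - lev[2]) / total
  c(min(max(w1, 0.02), 0.9), min(max(w2, 0.02), 0.9))
}

#' Single-curve multivariate kinetic analysis (sc-MKA) fit
#'
#' Fits the consecutive three-step model to one mass-loss curve by bounded
#' Levenberg-Marquardt least squares with the three activation energies
#' held fixed, leaving `log10_A`, `M`, `N` per step plus the weights `w1`,
#' `w2` (and optionally `delta_m`) free. The forward model is integrated on
#' the curve's own time grid (thinned to `max_fit_points`) under a linear
#' ramp through the curve's recorded temperature endpoints. A deterministic
#' multistart over the exponent grid guards against the multi-modality of
#' autocatalytic fits: every start is probed for `coarse_maxit` iterations
#' and the best is polished to convergence.
#'
#' @param curve a [tga_curve()] covering the full decomposition when
#'   `delta_m = "fixed_from_data"`.
#' @param spec a [fit_spec()].
#' @param start optional named list overriding the multistart: full start
#'   values for `log10_A` (3), `M` (3), `N` (3), `w1`, `w2` (and `delta_m`
#'   when free).
#' @return an object of class `scmka_fit`; see [coef.scmka_fit()],
#'   [predict.scmka_fit()], [residuals.scmka_fit()].
#' @export
fit_curve <- function(curve, spec, start = NULL) {
  stopifnot(inherits(curve, "tga_curve"), inherits(spec, "fit_spec"))
  n <- length(curve$t)
  program <- curve_program(curve)

  m0_pct <- mean(curve$m_pct[seq_len(max(3L, floor(0.01 * n)))])
  m_t0 <- spec$m_t0 %||% (m0_pct / 100)

  tail_idx <- seq.int(max(1L, n - max(3L, floor(0.02 * n))), n)
  if (identical(spec$delta_m, "fixed_from_data")) {
    last5 <- seq.int(floor(0.95 * n), n)
    # regression slope over the tail window (pointwise differences are
    # dominated by balance noise)
    slope <- coef(lm(m ~ T, data = list(m = curve$m_pct[last5],
                                        T = curve$T_C[last5])))[["T"]]
    if (abs(slope) > spec$plateau_tol)
      stop("curve does not reach a final plateau; cannot fix delta_m from data",
           call. = FALSE)
    delta_m_fixed <- mean(curve$m_pct[tail_idx]) / 100 - m_t0
    free_dm <- FALSE
  } else if (is.numeric(spec$delta_m)) {
    delta_m_fixed <- spec$delta_m
    free_dm <- FALSE
  } else {
    delta_m_fixed <- mean(curve$m_pct[tail_idx]) / 100 - m_t0 # start value
    free_dm <- TRUE
  }

  idx <- unique(round(seq(1, n, length.out = min(n, spec$max_fit_points))))
  t_fit <- curve$t[idx]
  y_obs <- curve$m_pct[idx]

  make_model <- function(p) {
    steps <- lapply(1:3, function(s)
      step_kinetics(spec$fixed_E[s], 10^p[[paste0("lA", s)]],
                    p[[paste0("M", s)]], p[[paste0("N", s)]]))
    w1 <- p[["w1"]]; w2 <- min(p[["w2"]], 1 - w1)
    dm <- if (free_dm) p[["dm"]] else delta_m_fixed
    consec_model(steps, w1 = w1, w2 = w2, delta_m = max(min(dm, 1), -1),
                 m_t0 = m_t0, conversion = spec$conversion)
  }
  resid_fn <- function(pv) {
    p <- as.list(pv)
    model <- make_model(p)
    # a failed integration at a pathological trial point is penalised, not
    # fatal: the optimizer backs off the step
    tr <- tryCatch(suppressWarnings(
      integrate_model(model, program, t_fit,
                      rtol = spec$rtol, atol = spec$atol)),
      error = function(e) NULL)
    if (is.null(tr)) return(rep(1e4, length(y_obs) + 1L))
    r <- y_obs - 100 * tr$m
    # soft constraint keeping w1 + w2 inside the simplex
    c(r, 1e3 * max(0, pv[["w1"]] + pv[["w2"]] - 1))
  }

  b <- spec$bounds
  lower <- c(rep(b$log10_A[1], 3), rep(b$M[1], 3), rep(b$N[1], 3),
             rep(b$w[1], 2))
  upper <- c(rep(b$log10_A[2], 3), rep(b$M[2], 3), rep(b$N[2], 3),
             rep(b$w[2], 2))
  pnames <- c(paste0("lA", 1:3), paste0("M", 1:3), paste0("N", 1:3),
              "w1", "w2")
  if (free_dm) {
    lower <- c(lower, -1); upper <- c(upper, 1); pnames <- c(pnames, "dm")
  }

  starts <- list()
  if (!is.null(start)) {
    sv <- c(start$log10_A, start$M, start$N, start$w1, start$w2,
            if (free_dm) start$delta_m)
    starts[[1]] <- setNames(sv, pnames)
  } else {
    peaks <- find_step_peaks(mass_derivative(curve), n_steps = 3)
    w_init <- init_weights(curve, peaks, m0_pct, delta_m_fixed)
    for (M0 in spec$multistart_M) for (N0 in spec$multistart_N) {
      lA <- init_log10A(curve, peaks, spec$fixed_E, M0, N0, w_init,
                        delta_m_fixed, b)
      sv <- c(lA, rep(clip(M0, b$M), 3), rep(clip(N0, b$N), 3),
              clip(w_init[1], b$w), clip(w_init[2], b$w),
              if (free_dm) delta_m_fixed)
      starts[[length(starts) + 1L]] <- setNames(sv, pnames)
    }
  }

  ctrl_coarse <- minpack.lm::nls.lm.control(maxiter = spec$coarse_maxit,
                                            ftol = spec$ftol, ptol = spec$ptol)
  ctrl_fine <- minpack.lm::nls.lm.control(maxiter = spec$maxit,
                                          ftol = spec$ftol, ptol = spec$ptol)
  diag_rows <- list()
  probes <- vector("list", length(starts))
  # lsoda's Fortran diagnostics for rejected trial points go to stdout;
  # keep the console clean while probing
  sink(nullfile()); on.exit(sink(), add = TRUE)
  rss_init <- vapply(starts, function(sv) sum(resid_fn(sv)^2), numeric(1))
  probe_set <- order(rss_init)[seq_len(min(length(starts),
                                           max(1L, spec$probe_top %||% length(starts))))]
  for (i in seq_along(starts)) {
    ok <- FALSE
    if (i %in% probe_set) {
      fit <- try(suppressWarnings(
        minpack.lm::nls.lm(par = starts[[i]], lower = lower,
                           upper = upper, fn = resid_fn,
                           control = if (length(starts) > 1) ctrl_coarse else ctrl_fine)),
                 silent = TRUE)
      ok <- !inherits(fit, "try-error")
      probes[[i]] <- if (ok) fit else NULL
    }
    diag_rows[[i]] <- data.frame(
      start = i,
      rss_init = rss_init[i],
      probed = i %in% probe_set,
      rss_probe = if (ok) fit$deviance else NA_real_,
      message = if (ok) fit$message else "not probed",
      stringsAsFactors = FALSE)
  }
  diag_df <- do.call(rbind, diag_rows)
  if (all(is.na(diag_df$rss_probe)))
    stop("no multistart converged; diagnostics:\n",
         paste(utils::capture.output(print(diag_df)), collapse = "\n"),
         call. = FALSE)
  best_i <- which.min(diag_df$rss_probe)
  best <- probes[[best_i]]
  if (length(starts) > 1) {
    polished <- try(suppressWarnings(
      minpack.lm::nls.lm(par = coef(best), lower = lower, upper = upper,
                         fn = resid_fn, control = ctrl_fine)), silent = TRUE)
    if (!inherits(polished, "try-error") && polished$deviance <= best$deviance)
      best <- polished
  }

  pv <- coef(best)
  model <- make_model(as.list(pv))
  tr <- integrate_model(model, program, t_fit, rtol = spec$rtol,
                        atol = spec$atol)
  y_cal <- 100 * tr$m
  structure(list(
    parameters = pv, model = model, fixed_E = spec$fixed_E,
    delta_m = model$delta_m, m_t0 = m_t0,
    rss = rss(y_obs, y_cal), fit_quality = fit_quality(y_obs, y_cal),
    residuals = y_obs - y_cal, fitted_values = y_cal,
    t_fit = t_fit, y_obs = y_obs, program = program, curve = curve,
    diagnostics = diag_df, winning_start = best_i,
    convergence = list(info = best$rinfo %||% NA, message = best$message,
                       niter = best$niter),
    spec = spec), class = "scmka_fit")
}

#' @export
print.scmka_fit <- function(x, ...) {
  cat(sprintf("sc-MKA fit: RSS = %.4g, r^2 = %.6f (%s)\n",
              x$rss, x$fit_quality, x$convergence$message))
  print(x$model)
  invisible(x)
}

#' @export
summary.scmka_fit <- function(object, ...) {
  cat(sprintf("sc-MKA fit of curve %s (q+ = %s C/min, %d fit points)\n",
              object$curve$meta$sample_id %||% "<unnamed>",
              format(object$curve$meta$q_plus_C_per_min %||% NA),
              length(object$t_fit)))
  cat(sprintf("fixed E: %s kJ/mol\n",
              paste(round(object$fixed_E / 1000, 1), collapse = ", ")))
  print(round(object$parameters, 4))
  cat(sprintf("delta_m = %.4f, RSS = %.4g, r^2 = %.6f, winning start %d\n",
              object$delta_m, object$rss, object$fit_quality,
              object$winning_start))
  invisible(object)
}

#' Extract fitted kinetic parameters
#' @param object an `scmka_fit`.
#' @param ... unused.
#' @return named numeric vector (`lA1..3`, `M1..3`, `N1..3`, `w1`, `w2`,
#'   plus `dm` when the total mass change was free).
#' @export
coef.scmka_fit <- function(object, ...) object$parameters

#' @export
residuals.scmka_fit <- function(object, ...) object$residuals

#' @export
fitted.scmka_fit <- function(object, ...) object$fitted_values

#' @export
plot.scmka_fit <- function(x, ...) {
  T_C <- K_to_C(temperature_at(x$program, x$t_fit))
  graphics::plot(T_C, x$y_obs, pch = ".", xlab = "temperature (°C)",
                 ylab = "mass (%)", ...)
  graphics::lines(T_C, x$fitted_values, col = 2)
  graphics::legend("topright", c("observed", "calculated"),
                   col = c(1, 2), lty = c(NA, 1), pch = c(20, NA), bty = "n")
  invisible(x)
}

#' Parameter-trend table across heating rates
#'
#' One row per fitted curve: the per-step kinetic parameters, the fixed
#' activation energies used, the proportional step representations
#' I1 = 100 w1, I2 = 100 w2, I3 = 100 (1 - w1 - w2) (percent of the total
#' mass loss), the total mass change in percent, and the fit quality.
#' Rows are sorted by (atmosphere, heating rate).
#'
#' @param fits list of `scmka_fit` objects.
#' @return data frame (`trend_table`).
#' @export
build_trend_table <- function(fits) {
  stopifnot(length(fits) >= 1)
  rows <- lapply(fits, function(f) {
    p <- f$parameters
    cur <- f$curve
    w1 <- p[["w1"]]; w2 <- min(p[["w2"]], 1 - p[["w1"]])
    data.frame(
      sample_id = cur$meta$sample_id %||% NA_character_,
      atmosphere = cur$meta$atmosphere %||% NA_character_,
      q_plus_C_per_min = cur$meta$q_plus_C_per_min %||% NA_real_,
      log10_A1 = p[["lA1"]], log10_A2 = p[["lA2"]], log10_A3 = p[["lA3"]],
      M1 = p[["M1"]], M2 = p[["M2"]], M3 = p[["M3"]],
      N1 = p[["N1"]], N2 = p[["N2"]], N3 = p[["N3"]],
      E1_used = f$fixed_E[1], E2_used = f$fixed_E[2], E3_used = f$fixed_E[3],
      I1 = 100 * w1, I2 = 100 * w2, I3 = 100 * (1 - w1 - w2),
      delta_m_pct = 100 * f$delta_m,
      fit_quality = f$fit_quality,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[order(out$atmosphere, out$q_plus_C_per_min), ]
  class(out) <- c("trend_table", "data.frame")
  out
}
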