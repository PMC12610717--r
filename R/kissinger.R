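#' Mass derivative of a TGA curve
#'
#' Estimates dm/dT at each interior grid temperature by local linear
#' regression of mass on temperature over a fixed-width window
#' `[T - delta_T/2, T + delta_T/2]`, which is robust to uneven sampling and
#' to point noise. Exact for data linear in T.
#'
#' @param curve a [tga_curve()] (ramp-type: temperature non-decreasing).
#' @param delta_T regression window width, degrees (default 2).
#' @return data frame with columns `T_C` (window centres) and `dm_dT`
#'   (percent per degree).
#' @export
mass_derivative <- function(curve, delta_T = 2) {
  stopifnot(inherits(curve, "tga_curve"))
  T_C <- curve$T_C
  m <- curve$m_pct
  if (any(diff(T_C) < 0))
    stop("temperature is not monotone; resample the curve before derivation",
         call. = FALSE)
  if (diff(range(T_C)) <= 2 * delta_T)
    stop("temperature span must exceed twice the derivative window",
         call. = FALSE)
  half <- delta_T / 2
  lo <- findInterval(T_C - half, T_C) + 1L
  hi <- findInterval(T_C + half, T_C)
  # rolling least-squares slope via cumulative sums
  cs1 <- cumsum(c(0, rep(1, length(T_C))))
  csx <- cumsum(c(0, T_C)); csy <- cumsum(c(0, m))
  csxx <- cumsum(c(0, T_C^2)); csxy <- cumsum(c(0, T_C * m))
  n <- cs1[hi + 1L] - cs1[lo]
  Sx <- csx[hi + 1L] - csx[lo]; Sy <- csy[hi + 1L] - csy[lo]
  Sxx <- csxx[hi + 1L] - csxx[lo]; Sxy <- csxy[hi + 1L] - csxy[lo]
  denom <- n * Sxx - Sx^2
  ok <- n >= 3 & denom > 1e-12
  slope <- rep(NA_real_, length(T_C))
  slope[ok] <- (n[ok] * Sxy[ok] - Sx[ok] * Sy[ok]) / denom[ok]
  keep <- ok & T_C >= T_C[1] + half & T_C <= T_C[length(T_C)] - half
  data.frame(T_C = T_C[keep], dm_dT = slope[keep])
}

# prominence of local minima: depth below the lower of the two highest
# barriers separating the minimum from deeper minima (or the series edges)
local_min_prominence <- function(y) {
  n <- length(y)
  cand <- which(diff(sign(diff(y))) > 0) + 1L
  if (length(cand) == 0L) return(data.frame(index = integer(), prominence = numeric()))
  prom <- vapply(cand, function(i) {
    jl <- i; barl <- -Inf
    while (jl > 1L) { jl <- jl - 1L; barl <- max(barl, y[jl]); if (y[jl] < y[i]) break }
    jr <- i; barr <- -Inf
    while (jr < n) { jr <- jr + 1L; barr <- max(barr, y[jr]); if (y[jr] < y[i]) break }
    min(barl, barr) - y[i]
  }, numeric(1))
  data.frame(index = cand, prominence = prom)
}

#' Locate step peaks in a mass-loss derivative
#'
#' Finds the `n_steps` most prominent local minima of dm/dT (i.e. maxima of
#' the mass-loss rate) above a prominence threshold, returned in order of
#' increasing temperature and indexed 1..n_steps.
#'
#' @param deriv data frame from [mass_derivative()].
#' @param n_steps number of decomposition steps expected (default 3).
#' @param prominence_frac minimum peak prominence as a fraction of the
#'   global maximum loss rate (default 0.05).
#' @param smooth_T optional moving-average half-width (degrees) applied to
#'   the derivative before peak picking (default 2; 0 disables).
#' @return data frame with columns `step_index`, `Tp_C`, `peak_dm_dT`.
#' @export
find_step_peaks <- function(deriv, n_steps = 3, prominence_frac = 0.05,
                            smooth_T = 2) {
  stopifnot(n_steps >= 1, is.data.frame(deriv))
  y <- deriv$dm_dT
  if (smooth_T > 0 && nrow(deriv) > 5) {
    dT <- stats::median(diff(deriv$T_C))
    k <- max(1L, round(smooth_T / max(dT, 1e-9)))
    if (k > 1) {
      kern <- rep(1 / (2 * k + 1), 2 * k + 1)
      y <- stats::filter(y, kern, sides = 2)
      y <- as.numeric(y)
    }
  }
  ok <- is.finite(y)
  yv <- y[ok]; Tv <- deriv$T_C[ok]
  max_rate <- max(-yv, 0)
  if (max_rate <= 0) stop("flat signal: no mass-loss peaks found", call. = FALSE)
  pm <- local_min_prominence(yv)
  pm <- pm[pm$prominence >= prominence_frac * max_rate, , drop = FALSE]
  if (nrow(pm) < n_steps)
    stop(sprintf("found only %d peak(s) above the prominence threshold (at %s C); %d required",
                 nrow(pm), paste(round(Tv[pm$index], 1), collapse = ", "),
                 n_steps), call. = FALSE)
  pm <- pm[order(-pm$prominence), , drop = FALSE][seq_len(n_steps), , drop = FALSE]
  pm <- pm[order(Tv[pm$index]), , drop = FALSE]
  data.frame(step_index = seq_len(n_steps), Tp_C = Tv[pm$index],
             peak_dm_dT = yv[pm$index])
}

#' Peak-temperature table for a set of curves
#'
#' Runs [mass_derivative()] and [find_step_peaks()] on every curve and
#' assembles the per-step peak temperatures across heating rates.
#'
#' @param curves list of [tga_curve()] objects (ramp scans).
#' @param n_steps steps per curve.
#' @param delta_T derivative window, degrees.
#' @param prominence_frac passed to [find_step_peaks()].
#' @return data frame with columns `sample_id`, `atmosphere`,
#'   `q_plus_C_per_min`, `step_index`, `Tp_C`, `Tp_K`, `peak_dm_dT`.
#' @export
peak_table <- function(curves, n_steps = 3, delta_T = 2,
                       prominence_frac = 0.05) {
  rows <- lapply(curves, function(cur) {
    pk <- find_step_peaks(mass_derivative(cur, delta_T), n_steps,
                          prominence_frac)
    data.frame(sample_id = cur$meta$sample_id %||% NA_character_,
               atmosphere = cur$meta$atmosphere %||% NA_character_,
               q_plus_C_per_min = cur$meta$q_plus_C_per_min %||% NA_real_,
               pk, Tp_K = C_to_K(pk$Tp_C), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$atmosphere, out$step_index, out$q_plus_C_per_min), ]
}

kissinger_xy <- function(q_C_min, Tp_K) {
  q_K_s <- rate_to_K_s(q_C_min) # unit change shifts the intercept only
  list(x = 1 / Tp_K, y = log(q_K_s / Tp_K^2))
}

#' Kissinger activation-energy fit (linear)
#'
#' Ordinary least squares of \eqn{y = \ln(q^+ / T_p^2)} on \eqn{x = 1/T_p}
#' across heating rates; the activation energy is \eqn{E = -R \cdot slope}.
#' Heating rates are converted to K/s internally, which changes only the
#' intercept, never the slope.
#'
#' @param points data frame with columns `q_plus_C_per_min` and `Tp_K` for
#'   one decomposition step (>= 3 rows, distinct Tp).
#' @return a `kissinger_result` with mode `"linear"`: fields `E` (J/mol),
#'   `intercept`, `r_squared`, `validity_window` (kelvin range of the Tp).
#' @export
kissinger_fit <- function(points) {
  if (nrow(points) < 3) stop("at least 3 (q+, Tp) points required", call. = FALSE)
  if (anyDuplicated(points$Tp_K)) stop("duplicated Tp values: singular fit", call. = FALSE)
  stopifnot(all(points$q_plus_C_per_min > 0))
  d <- kissinger_xy(points$q_plus_C_per_min, points$Tp_K)
  fit <- lm(y ~ x, data = d)
  structure(list(mode = "linear",
                 E = -coef(fit)[["x"]] * R_gas,
                 intercept = coef(fit)[["(Intercept)"]],
                 r_squared = 1 - sum(residuals(fit)^2) /
                   sum((d$y - mean(d$y))^2),
                 validity_window = range(points$Tp_K),
                 points = points, fit = fit),
            class = "kissinger_result")
}

#' Quadratic Kissinger fit for curved plots
#'
#' Fits \eqn{y = a + b x + c x^2} in the Kissinger coordinates
#' (\eqn{x = 1/T_p}); the temperature-dependent activation energy is the
#' derivative of the fit, \eqn{E(T) = -R (b + 2c/T)}, valid over the
#' observed Tp range.
#'
#' @param points as for [kissinger_fit()] (>= 4 rows).
#' @return a `kissinger_result` with mode `"quadratic"`: coefficients
#'   `a`, `b`, `c`, plus `r_squared` and `validity_window`.
#' @export
kissinger_quadratic <- function(points) {
  if (nrow(points) < 4) stop("at least 4 points required for the quadratic fit",
                             call. = FALSE)
  if (anyDuplicated(points$Tp_K)) stop("duplicated Tp values: singular fit", call. = FALSE)
  d <- kissinger_xy(points$q_plus_C_per_min, points$Tp_K)
  fit <- lm(y ~ x + I(x^2), data = d)
  cf <- coef(fit)
  structure(list(mode = "quadratic",
                 a = cf[["(Intercept)"]], b = cf[["x"]], c = cf[["I(x^2)"]],
                 r_squared = 1 - sum(residuals(fit)^2) /
                   sum((d$y - mean(d$y))^2),
                 validity_window = range(points$Tp_K),
                 points = points, fit = fit),
            class = "kissinger_result")
}

#' Evaluate activation energy from a Kissinger result
#'
#' Linear mode returns the constant E; quadratic mode evaluates
#' \eqn{E(T) = -R (b + 2c/T)}. Evaluation outside the validity window is an
#' error unless `clamp = TRUE` (clamping to the window edge is the caller's
#' explicit choice).
#'
#' @param result a `kissinger_result`.
#' @param T_K temperature(s), kelvin.
#' @param clamp clamp to the validity window instead of erroring.
#' @return activation energy value(s), J/mol.
#' @export
activation_energy_at <- function(result, T_K, clamp = FALSE) {
  stopifnot(inherits(result, "kissinger_result"))
  if (result$mode == "linear") return(rep(result$E, length(T_K)))
  w <- result$validity_window
  if (!clamp && (any(T_K < w[1] - 1e-9) || any(T_K > w[2] + 1e-9)))
    stop("temperature outside the E(T) validity window", call. = FALSE)
  Tc <- pmin(pmax(T_K, w[1]), w[2])
  -R_gas * (result$b + 2 * result$c / Tc)
}

#' Choose between constant and temperature-dependent activation energy
#'
#' Deterministic rule: the quadratic mode is adopted iff the extra-sum-of-
#' squares F-test for the quadratic term is significant at
#' `curvature_threshold` AND the implied E(T) stays positive over the Tp
#' window; a p-value exactly at the threshold counts as quadratic.
#'
#' @param points as for [kissinger_fit()] (>= 4 rows).
#' @param curvature_threshold significance level (default 0.05).
#' @return `"linear"` or `"quadratic"`.
#' @export
select_E_mode <- function(points, curvature_threshold = 0.05) {
  if (nrow(points) < 4) return("linear")
  lin <- kissinger_fit(points)
  qd <- kissinger_quadratic(points)
  rss_lin <- sum(residuals(lin$fit)^2)
  rss_qd <- sum(residuals(qd$fit)^2)
  if (rss_qd < .Machine$double.eps * max(1, rss_lin)) {
    # numerically exact quadratic (or collinear) data: fall back on r^2 gain
    p <- if (rss_lin > 1e-20) 0 else 1
  } else {
    df2 <- nrow(points) - 3
    Fstat <- (rss_lin - rss_qd) / (rss_qd / df2)
    p <- pf(Fstat, 1, df2, lower.tail = FALSE)
  }
  Tt <- seq(qd$validity_window[1], qd$validity_window[2], length.out = 64)
  if (p <= curvature_threshold && all(activation_energy_at(qd, Tt) > 0))
    "quadratic" else "linear"
}

#' Kissinger analysis of a curve set
#'
#' The high-level driver: computes derivative curves, locates per-step peak
#' temperatures across heating rates, and fits each step's Kissinger plot,
#' automatically selecting the linear or quadratic (temperature-dependent E)
#' form per step and atmosphere via [select_E_mode()].
#'
#' @param curves list of [tga_curve()] (one atmosphere or several).
#' @param n_steps decomposition steps per curve.
#' @param delta_T derivative window, degrees.
#' @param prominence_frac peak prominence threshold.
#' @param curvature_threshold passed to [select_E_mode()].
#' @return a `kissinger_analysis`: list with `peaks` (the peak table) and
#'   `fits`, a list keyed by `atmosphere.step` of `kissinger_result` objects.
#' @export
kissinger_analysis <- function(curves, n_steps = 3, delta_T = 2,
                               prominence_frac = 0.05,
                               curvature_threshold = 0.05) {
  pk <- peak_table(curves, n_steps, delta_T, prominence_frac)
  fits <- list()
  for (atm in unique(pk$atmosphere)) {
    for (s in seq_len(n_steps)) {
      pts <- pk[pk$atmosphere %in% atm & pk$step_index == s,
                c("q_plus_C_per_min", "Tp_K")]
      mode <- if (nrow(pts) >= 4) select_E_mode(pts, curvature_threshold) else "linear"
      fits[[paste(atm, s, sep = ".")]] <-
        if (mode == "quadratic") kissinger_quadratic(pts) else kissinger_fit(pts)
    }
  }
  structure(list(peaks = pk, fits = fits, n_steps = n_steps),
            class = "kissinger_analysis")
}

#' @export
print.kissinger_result <- function(x, ...) {
  if (x$mode == "linear")
    cat(sprintf("Kissinger fit (linear): E = %.1f kJ/mol, r^2 = %.5f\n",
                x$E / 1000, x$r_squared))
  else
    cat(sprintf(
      "Kissinger fit (quadratic): E(T) = -R(b + 2c/T), b = %.4g, c = %.4g, valid %.1f-%.1f K\n",
      x$b, x$c, x$validity_window[1], x$validity_window[2]))
  invisible(x)
}

#' @export
print.kissinger_analysis <- function(x, ...) {
  cat("Kissinger analysis:", length(x$fits), "step fits\n")
  for (nm in names(x$fits)) {
    cat(" ", nm, ": ")
    print(x$fits[[nm]])
  }
  invisible(x)
}

#' @export
plot.kissinger_analysis <- function(x, ...) {
  d <- kissinger_xy(x$peaks$q_plus_C_per_min, x$peaks$Tp_K)
  graphics::plot(d$x, d$y, pch = x$peaks$step_index,
                 col = as.integer(factor(x$peaks$atmosphere)),
                 xlab = "1/Tp (1/K)", ylab = "ln(q+/Tp^2)", ...)
  invisible(x)
}

#' Per-curve fixed activation energies from a Kissinger analysis
#'
#' The hand-off to per-curve fitting: for constant-E steps the fitted E; for
#' temperature-dependent steps the value E(Tp) evaluated at that specific
#' curve's peak temperature.
#'
#' @param ka a `kissinger_analysis`.
#' @param sample_id curve identifier present in the peak table.
#' @return numeric vector of length `n_steps`, J/mol.
#' @export
fixed_E_for_curve <- function(ka, sample_id) {
  stopifnot(inherits(ka, "kissinger_analysis"))
  pk <- ka$peaks[ka$peaks$sample_id == sample_id, ]
  if (nrow(pk) == 0) stop("unknown sample_id: ", sample_id, call. = FALSE)
  atm <- pk$atmosphere[1]
  vapply(seq_len(ka$n_steps), function(s) {
    res <- ka$fits[[paste(atm, s, sep = ".")]]
    Tp <- pk$Tp_K[pk$step_index == s]
    if (res$mode == "linear") res$E
    else activation_energy_at(res, Tp, clamp = TRUE)
  }, numeric(1))
}
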