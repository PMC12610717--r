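#' TGA mass-loss curve
#'
#' A sampled thermogravimetric record: time, furnace temperature and relative
#' sample mass (percent of initial mass), plus run metadata.
#'
#' @param t time, seconds; strictly increasing, length >= 10.
#' @param T_C temperature, degrees Celsius; non-decreasing for ramp runs.
#' @param m_pct relative mass, percent of initial mass, in (0, 120].
#' @param meta named list of metadata; recognised fields are `sample_id`,
#'   `atmosphere`, `q_plus_C_per_min`, `initial_mass_mg`, `seed` and (for
#'   synthetic curves) `truth`, the realised generating parameters.
#' @return a `tga_curve` object.
#' @export
tga_curve <- function(t, T_C, m_pct, meta = list()) {
  n <- length(t)
  if (n < 10L || length(T_C) != n || length(m_pct) != n)
    stop("t, T_C and m_pct must have equal length >= 10", call. = FALSE)
  if (any(!is.finite(t)) || any(!is.finite(T_C)) || any(!is.finite(m_pct)))
    stop("curve arrays must be finite (no NaN)", call. = FALSE)
  if (any(diff(t) <= 0))
    stop("time must be strictly increasing", call. = FALSE)
  if (any(m_pct <= 0) || any(m_pct > 120))
    stop("mass_pct must lie in (0, 120]", call. = FALSE)
  structure(list(t = t, T_C = T_C, m_pct = m_pct, meta = meta),
            class = "tga_curve")
}

#' @export
print.tga_curve <- function(x, ...) {
  cat(sprintf("TGA curve: %d points, %.1f-%.1f C, mass %.2f -> %.2f %%\n",
              length(x$t), min(x$T_C), max(x$T_C),
              x$m_pct[1], x$m_pct[length(x$m_pct)]))
  if (!is.null(x$meta$atmosphere) || !is.null(x$meta$q_plus_C_per_min))
    cat(sprintf("  atmosphere: %s, nominal q+ = %s C/min\n",
                x$meta$atmosphere %||% "?",
                format(x$meta$q_plus_C_per_min %||% NA)))
  invisible(x)
}

#' @export
plot.tga_curve <- function(x, ...) {
  graphics::plot(x$T_C, x$m_pct, type = "l", xlab = "temperature (°C)",
                 ylab = "mass (% of initial)", ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
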