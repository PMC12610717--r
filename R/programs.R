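#' Temperature unit helpers
#'
#' Internally the package works exclusively in kelvin and seconds; degrees
#' Celsius and degrees-per-minute heating rates appear only at input/output
#' boundaries. These helpers perform the conversions at those boundaries.
#'
#' @param T_C,T_K temperature in degrees Celsius / kelvin.
#' @param q_C_min heating rate in degrees Celsius per minute.
#' @param rate_K_s heating rate in kelvin per second.
#' @return a numeric vector in the target unit.
#' @examples
#' C_to_K(25)
#' rate_to_K_s(10) # 10 C/min
#' @export
C_to_K <- function(T_C) T_C + 273.15

#' @rdname C_to_K
#' @export
K_to_C <- function(T_K) T_K - 273.15

#' @rdname C_to_K
#' @export
rate_to_K_s <- function(q_C_min) q_C_min / 60

#' @rdname C_to_K
#' @export
rate_to_C_min <- function(rate_K_s) rate_K_s * 60

new_segment <- function(kind, T_start, T_end = NA_real_, rate = NA_real_,
                        duration = NA_real_) {
  stopifnot(kind %in% c("ramp", "hold"))
  if (T_start <= 0) stop("segment temperatures must be positive kelvin", call. = FALSE)
  if (kind == "ramp") {
    if (!is.finite(rate) || rate <= 0)
      stop("ramp rate must be a positive finite K/s value", call. = FALSE)
    if (!is.finite(T_end) || T_end <= T_start)
      stop("ramp end temperature must exceed start temperature", call. = FALSE)
    duration <- (T_end - T_start) / rate
  } else {
    if (!is.finite(duration) || duration <= 0)
      stop("hold duration must be positive", call. = FALSE)
    T_end <- T_start
  }
  list(kind = kind, T_start = T_start, T_end = T_end, rate = rate,
       duration = duration)
}

new_heating_program <- function(segments) {
  if (length(segments) == 0L) stop("program needs at least one segment", call. = FALSE)
  for (i in seq_along(segments)[-1]) {
    if (abs(segments[[i]]$T_start - segments[[i - 1L]]$T_end) > 1e-9)
      stop("segments must be contiguous in temperature", call. = FALSE)
  }
  dur <- vapply(segments, `[[`, numeric(1), "duration")
  structure(list(segments = segments,
                 origin_temperature = segments[[1L]]$T_start,
                 t_bounds = c(0, cumsum(dur)),
                 total_duration = sum(dur)),
            class = "heating_program")
}

#' Linear heating ramp program
#'
#' Builds a single-segment thermal protocol heating linearly from `T_start`
#' to `T_end` at a constant rate, as used in non-isothermal TGA scans.
#'
#' @param T_start,T_end start and end temperatures, kelvin (`T_end > T_start`).
#' @param rate heating rate in kelvin per second (> 0).
#' @return a `heating_program` object.
#' @examples
#' pr <- make_linear_ramp(C_to_K(30), C_to_K(550), rate_to_K_s(10))
#' program_duration(pr) # 3120 s
#' @seealso [make_ramp_hold()], [temperature_at()]
#' @export
make_linear_ramp <- function(T_start, T_end, rate) {
  new_heating_program(list(new_segment("ramp", T_start, T_end = T_end, rate = rate)))
}

#' Ramp-then-hold program
#'
#' A heating ramp from `T_start` to `T_hold` followed by an isothermal hold,
#' the protocol used for processing-condition predictions (e.g. an oven ramp
#' preceding an isothermal anneal). When `T_hold == T_start` the ramp has zero
#' length and the program collapses to a pure isothermal hold.
#'
#' @param T_start ramp start temperature, kelvin.
#' @param T_hold hold temperature, kelvin (`>= T_start`).
#' @param rate ramp heating rate, K/s (ignored when the ramp has zero length).
#' @param hold_duration hold time in seconds (> 0).
#' @return a `heating_program` object.
#' @examples
#' make_ramp_hold(C_to_K(30), C_to_K(230), rate_to_K_s(5), 3600)
#' make_ramp_hold(C_to_K(230), C_to_K(230), rate_to_K_s(5), 600) # pure hold
#' @export
make_ramp_hold <- function(T_start, T_hold, rate, hold_duration) {
  if (T_hold < T_start)
    stop("hold temperature must not be below the ramp start", call. = FALSE)
  segs <- list()
  if (T_hold > T_start)
    segs <- list(new_segment("ramp", T_start, T_end = T_hold, rate = rate))
  segs <- c(segs, list(new_segment("hold", T_hold, duration = hold_duration)))
  new_heating_program(segs)
}

#' Total duration of a heating program
#' @param program a `heating_program`.
#' @return duration in seconds.
#' @export
program_duration <- function(program) {
  stopifnot(inherits(program, "heating_program"))
  program$total_duration
}

#' Evaluate a heating program
#'
#' Piecewise-linear, continuous temperature as a function of time. Queries
#' outside `[0, program_duration(program)]` are an error: the protocol is not
#' extrapolated.
#'
#' @param program a `heating_program`.
#' @param t time(s) in seconds since the start of the program.
#' @return temperature(s) in kelvin, same length as `t`.
#' @examples
#' pr <- make_linear_ramp(303.15, 823.15, rate_to_K_s(10))
#' temperature_at(pr, 60) # 313.15 K
#' @export
temperature_at <- function(program, t) {
  stopifnot(inherits(program, "heating_program"))
  if (any(!is.finite(t)) || any(t < -1e-9) ||
      any(t > program$total_duration + 1e-9))
    stop("time outside [0, total duration]; programs are not extrapolated",
         call. = FALSE)
  t <- pmin(pmax(t, 0), program$total_duration)
  idx <- findInterval(t, program$t_bounds, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(program$segments))
  out <- numeric(length(t))
  for (i in seq_along(t)) {
    seg <- program$segments[[idx[i]]]
    t_local <- t[i] - program$t_bounds[idx[i]]
    out[i] <- if (seg$kind == "ramp") seg$T_start + seg$rate * t_local else seg$T_start
  }
  out
}

#' @export
print.heating_program <- function(x, ...) {
  cat("Heating program:", length(x$segments), "segment(s), total",
      format(x$total_duration), "s\n")
  for (seg in x$segments) {
    if (seg$kind == "ramp")
      cat(sprintf("  ramp  %7.2f -> %7.2f C at %g C/min (%g s)\n",
                  K_to_C(seg$T_start), K_to_C(seg$T_end),
                  rate_to_C_min(seg$rate), seg$duration))
    else
      cat(sprintf("  hold  %7.2f C for %g s\n", K_to_C(seg$T_start), seg$duration))
  }
  invisible(x)
}

# Flatten a program into the fixed-width parameter layout consumed by the
# compiled ODE right-hand side: [n_seg, then per segment (t0, t1, T0, rate)].
# Maximum 4 segments; enough for ramp and ramp+hold protocols.
program_parms <- function(program) {
  n <- length(program$segments)
  if (n > 4L) stop("compiled integrator supports at most 4 segments", call. = FALSE)
  p <- numeric(1L + 4L * 4L)
  p[1] <- n
  for (i in seq_len(n)) {
    seg <- program$segments[[i]]
    off <- 1L + (i - 1L) * 4L
    p[off + 1L] <- program$t_bounds[i]
    p[off + 2L] <- program$t_bounds[i + 1L]
    p[off + 3L] <- seg$T_start
    p[off + 4L] <- if (seg$kind == "ramp") seg$rate else 0
  }
  p
}
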