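#' Prediction protocol
#'
#' A processing-relevant thermal protocol: an isothermal hold, optionally
#' preceded by a heating ramp from a lower start temperature (e.g. an
#' extrusion pre-heat at 5 C/min). Conversion is reported on a clock that
#' starts at the hold onset; ramp-accumulated conversion is reported
#' separately.
#'
#' @param hold_temperature_C hold temperature, degrees Celsius.
#' @param hold_duration hold time, seconds (> 0).
#' @param ramp optional list `list(start_C = , rate_C_min = )` describing
#'   the preceding heating ramp (start below the hold temperature).
#' @param resolution output resolution during the hold, seconds.
#' @return a `prediction_protocol` object.
#' @examples
#' prediction_protocol(230, 3600)
#' prediction_protocol(230, 3600, ramp = list(start_C = 30, rate_C_min = 5))
#' @export
prediction_protocol <- function(hold_temperature_C, hold_duration,
                                ramp = NULL, resolution = 1) {
  stopifnot(hold_duration > 0, resolution > 0)
  if (!is.null(ramp)) {
    stopifnot(is.list(ramp), !is.null(ramp$start_C), !is.null(ramp$rate_C_min))
    if (ramp$start_C >= hold_temperature_C)
      stop("ramp must start below the hold temperature", call. = FALSE)
  }
  structure(list(hold_temperature_C = hold_temperature_C,
                 hold_duration = hold_duration, ramp = ramp,
                 resolution = resolution),
            class = "prediction_protocol")
}

protocol_program <- function(protocol) {
  T_hold <- C_to_K(protocol$hold_temperature_C)
  if (is.null(protocol$ramp))
    make_ramp_hold(T_hold, T_hold, 1, protocol$hold_duration)
  else
    make_ramp_hold(C_to_K(protocol$ramp$start_C), T_hold,
                   rate_to_K_s(protocol$ramp$rate_C_min),
                   protocol$hold_duration)
}

#' Predict decomposition under a processing protocol
#'
#' Integrates a consecutive model over the protocol (ramp, if any, then
#' hold) and reports the conversion trajectory on the hold clock. The
#' conversion is the total-mass-loss-normalised progress (alpha = m_rel);
#' when the model carries a total mass change, percent mass loss
#' `|delta_m| * m_rel * 100` is reported alongside.
#'
#' @param object a [consec_model()] (method for `predict()`), or an
#'   `scmka_fit` whose fitted model is used.
#' @param protocol a [prediction_protocol()].
#' @param thresholds conversion thresholds for time-to-threshold reporting
#'   (default 0.001, 0.01, 0.05).
#' @param ... unused.
#' @return a `tga_prediction`: list with `time` (s, from hold onset),
#'   `alpha`, `mass_loss_pct`, `pre_conversion` (conversion accumulated
#'   during the ramp), `time_to_thresholds` (named vector, `NA` when not
#'   reached within the hold), and `protocol`.
#' @export
predict.consec_model <- function(object, protocol,
                                 thresholds = c(0.001, 0.01, 0.05), ...) {
  stopifnot(inherits(protocol, "prediction_protocol"))
  program <- protocol_program(protocol)
  t_hold0 <- program$total_duration - protocol$hold_duration
  grid_hold <- seq(0, protocol$hold_duration, by = protocol$resolution)
  if (grid_hold[length(grid_hold)] < protocol$hold_duration)
    grid_hold <- c(grid_hold, protocol$hold_duration)
  grid <- t_hold0 + grid_hold
  if (grid[1] <= 0) grid[1] <- min(1e-9, grid[2] / 2)
  tr <- integrate_model(object, program, grid)
  alpha <- tr$m_rel
  pre <- if (t_hold0 > 0) alpha[1] else 0
  ttt <- vapply(thresholds, function(th) {
    i <- which(alpha >= th)
    if (length(i) == 0) return(NA_real_)
    i <- i[1]
    if (i == 1) return(grid_hold[1])
    # linear interpolation between bracketing grid points
    t0 <- grid_hold[i - 1]; t1 <- grid_hold[i]
    a0 <- alpha[i - 1]; a1 <- alpha[i]
    if (a1 == a0) t1 else t0 + (th - a0) / (a1 - a0) * (t1 - t0)
  }, numeric(1))
  structure(list(time = grid_hold, alpha = alpha,
                 mass_loss_pct = 100 * abs(object$delta_m) * alpha,
                 pre_conversion = pre,
                 time_to_thresholds = setNames(ttt, as.character(thresholds)),
                 protocol = protocol),
            class = "tga_prediction")
}

#' @rdname predict.consec_model
#' @export
predict.scmka_fit <- function(object, protocol, ...) {
  predict(object$model, protocol, ...)
}

#' @export
print.tga_prediction <- function(x, ...) {
  p <- x$protocol
  cat(sprintf("Prediction: hold at %.0f C for %.0f s%s\n",
              p$hold_temperature_C, p$hold_duration,
              if (is.null(p$ramp)) "" else
                sprintf(" after ramp from %.0f C at %g C/min",
                        p$ramp$start_C, p$ramp$rate_C_min)))
  cat(sprintf("  conversion at end of hold: %.5g (pre-conversion %.3g)\n",
              x$alpha[length(x$alpha)], x$pre_conversion))
  for (nm in names(x$time_to_thresholds)) {
    v <- x$time_to_thresholds[[nm]]
    cat(sprintf("  time to alpha = %s: %s\n", nm,
                if (is.na(v)) "not reached" else sprintf("%.1f s", v)))
  }
  invisible(x)
}

#' @export
plot.tga_prediction <- function(x, ...) {
  graphics::plot(x$time / 60, x$alpha, type = "l", xlab = "hold time (min)",
                 ylab = "conversion", ...)
  invisible(x)
}

#' Time to reach a conversion threshold
#'
#' First crossing time of the hold-clock conversion trajectory, by linear
#' interpolation between the bracketing grid points; `NA` when the
#' threshold is not reached within the hold.
#'
#' @param result a `tga_prediction`.
#' @param threshold conversion fraction in (0, 1).
#' @return time in seconds, or `NA` (not reached).
#' @export
time_to_conversion <- function(result, threshold) {
  stopifnot(inherits(result, "tga_prediction"))
  if (!is.finite(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly between 0 and 1", call. = FALSE)
  a <- result$alpha; tt <- result$time
  i <- which(a >= threshold)
  if (length(i) == 0) return(NA_real_)
  i <- i[1]
  if (i == 1) return(tt[1])
  t0 <- tt[i - 1]; t1 <- tt[i]; a0 <- a[i - 1]; a1 <- a[i]
  if (a1 == a0) t1 else t0 + (threshold - a0) / (a1 - a0) * (t1 - t0)
}

#' Compare prediction bases
#'
#' Evaluates several kinetic parameter bases (e.g. fits obtained at
#' different heating rates or atmospheres) under the same set of protocols
#' and tabulates the conversion at fixed report times plus the time to 1 %
#' conversion, with ratio columns against a declared reference basis.
#'
#' @param models named list of [consec_model()] objects (>= 2), the bases.
#' @param protocols list of [prediction_protocol()] objects.
#' @param reference name of the reference basis (default: first).
#' @param report_times_s report times on the hold clock, seconds.
#' @return data frame with one row per (basis, protocol, report time):
#'   conversion, conversion ratio vs reference, and per (basis, protocol)
#'   the time to 1 % with its ratio.
#' @export
compare_bases <- function(models, protocols,
                          reference = names(models)[1],
                          report_times_s = c(30, 60, 300, 900, 3600)) {
  stopifnot(length(models) >= 2, !is.null(names(models)))
  if (!reference %in% names(models))
    stop("unknown reference basis: ", reference, call. = FALSE)
  if (inherits(protocols, "prediction_protocol")) protocols <- list(protocols)
  rows <- list()
  for (pi in seq_along(protocols)) {
    prot <- protocols[[pi]]
    preds <- lapply(models, predict, protocol = prot)
    a_ref <- approx(preds[[reference]]$time, preds[[reference]]$alpha,
                    xout = report_times_s, rule = 2)$y
    t1_ref <- time_to_conversion(preds[[reference]], 0.01)
    for (b in names(models)) {
      a_b <- approx(preds[[b]]$time, preds[[b]]$alpha,
                    xout = report_times_s, rule = 2)$y
      t1_b <- time_to_conversion(preds[[b]], 0.01)
      rows[[length(rows) + 1L]] <- data.frame(
        basis = b, protocol = pi,
        hold_temperature_C = prot$hold_temperature_C,
        report_time_s = report_times_s,
        alpha = a_b, alpha_ratio = a_b / pmax(a_ref, 1e-300),
        time_to_1pct_s = t1_b, time_to_1pct_ratio = t1_b / t1_ref,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
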