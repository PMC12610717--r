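#' Noise specification for synthetic TGA curves
#'
#' Emulates the reproducibility of a multi-heating-rate TGA study: a
#' per-curve systematic offset along the temperature axis, relative
#' perturbations of the step-magnitude weights and of the overall mass loss
#' (both act on the generating parameters of the curve, mimicking sample-to-
#' sample variation), and per-point balance noise on the mass signal.
#'
#' @param mass_sigma standard deviation of per-point mass noise, as a
#'   fraction of the initial mass (default 5e-4, i.e. 0.05 %).
#' @param temp_jitter_C half-width of the uniform per-curve temperature-axis
#'   offset, degrees Celsius (default 2).
#' @param step_magnitude_rel_sigma relative (Gaussian) perturbation of the
#'   step weights w1, w2 (default 0.03).
#' @param total_loss_rel_sigma relative perturbation of the total mass change
#'   delta_m (default 0.02).
#' @param seed integer seed; mandatory whenever any sigma is non-zero.
#' @return a `noise_spec` object.
#' @export
noise_spec <- function(mass_sigma = 5e-4, temp_jitter_C = 2,
                       step_magnitude_rel_sigma = 0.03,
                       total_loss_rel_sigma = 0.02, seed = NULL) {
  sig <- c(mass_sigma, temp_jitter_C, step_magnitude_rel_sigma,
           total_loss_rel_sigma)
  if (any(sig < 0)) stop("noise sigmas must be >= 0", call. = FALSE)
  if (any(sig > 0) && is.null(seed))
    stop("a seed is mandatory for any non-zero noise", call. = FALSE)
  structure(list(mass_sigma = mass_sigma, temp_jitter_C = temp_jitter_C,
                 step_magnitude_rel_sigma = step_magnitude_rel_sigma,
                 total_loss_rel_sigma = total_loss_rel_sigma,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "noise_spec")
}

#' Noise-free specification
#' @return a `noise_spec` with all sigmas zero.
#' @export
no_noise <- function() noise_spec(0, 0, 0, 0, seed = NULL)

#' Built-in synthetic truth models
#'
#' Two fixture parameter sets standing in for decomposition under inert
#' ("N2") and oxidising ("air") atmospheres. They are synthetic stand-ins
#' chosen so that at 10 C/min the three mass-loss-rate peaks fall near
#' 275, 315 and 350 C with realistic overlap, and the step magnitudes and
#' total losses match a three-plateau pattern (circa 100 -> 88 -> 44 -> 9 %
#' for "N2", 100 -> 88 -> 57 -> 20 % for "air"). They are not fitted values
#' for any real substance.
#'
#' @param atmosphere `"N2"` or `"air"`.
#' @return a [consec_model()].
#' @export
default_model <- function(atmosphere = c("N2", "air")) {
  atmosphere <- match.arg(atmosphere)
  p <- if (atmosphere == "N2")
    list(E = c(165e3, 190e3, 220e3), lA = c(14.172, 15.318, 16.806),
         M = c(0.5, 0.5, 0.5), N = c(1.2, 1.4, 1.5),
         w1 = 0.13, w2 = 0.48, dm = -0.91)
  else
    list(E = c(160e3, 180e3, 205e3), lA = c(13.758, 14.565, 15.665),
         M = c(0.45, 0.55, 0.5), N = c(1.2, 1.5, 1.6),
         w1 = 0.15, w2 = 0.39, dm = -0.80)
  steps <- mapply(function(e, a, m, n) step_kinetics(e, 10^a, m, n),
                  p$E, p$lA, p$M, p$N, SIMPLIFY = FALSE)
  consec_model(steps, w1 = p$w1, w2 = p$w2, delta_m = p$dm)
}

#' Study design for synthetic data generation
#'
#' The measurement series being emulated: linear heating scans over a fixed
#' temperature span at a set of heating rates, one fresh sample per scan,
#' under two atmospheres represented by two truth parameter sets.
#'
#' @param q_list heating rates, C/min (default the ten rates 0.1-20 used in
#'   the emulated design).
#' @param T_span_C scan temperature span, C (default 30-550).
#' @param sampling_interval nominal sampling interval, seconds; each curve is
#'   capped at `max_points` samples, so slow scans are sampled more coarsely.
#' @param atmosphere_models named list mapping atmosphere label to the
#'   generating [consec_model()].
#' @param max_points per-curve cap on the number of samples.
#' @return a `study_design` object.
#' @export
study_design <- function(q_list = c(0.1, 0.2, 0.5, 1, 2, 3, 5, 7, 10, 20),
                         T_span_C = c(30, 550), sampling_interval = 1,
                         atmosphere_models = list(N2 = default_model("N2"),
                                                  air = default_model("air")),
                         max_points = 20000L) {
  stopifnot(all(q_list > 0), !anyDuplicated(q_list),
            length(T_span_C) == 2L, T_span_C[2] > T_span_C[1],
            sampling_interval > 0, length(atmosphere_models) >= 1)
  structure(list(q_list = q_list, T_span_C = T_span_C,
                 sampling_interval = sampling_interval,
                 atmosphere_models = atmosphere_models,
                 max_points = as.integer(max_points)),
            class = "study_design")
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

# Deterministic seed splitting: curve i of a study seeded with `seed` uses
# seed*1000 + i (mod .Machine$integer.max), recorded in the manifest so any
# single curve can be regenerated bit-exactly.
split_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1000 + index) %% .Machine$integer.max)
}

#' Generate one synthetic TGA curve
#'
#' Integrates the forward model under `program` and applies the noise model:
#' the step weights and total mass change are perturbed once per curve (they
#' become the curve's own realised truth, recorded in `meta$truth`), the
#' temperature axis is shifted by a single per-curve offset, and per-point
#' Gaussian noise is added to the mass. With all sigmas zero the curve
#' equals the [integrate_model()] output exactly on the same grid.
#'
#' @param model generating [consec_model()].
#' @param program a `heating_program`.
#' @param sampling_interval seconds between samples (curve capped at
#'   `max_points`).
#' @param noise a [noise_spec()].
#' @param meta extra metadata stored on the curve.
#' @param max_points per-curve sample cap.
#' @return a [tga_curve()] whose `meta$truth` holds the realised generating
#'   parameters (per-step E, log10_A, M, N plus w1, w2, delta_m, the
#'   temperature offset, and the seed).
#' @export
generate_curve <- function(model, program, sampling_interval = 1,
                           noise = no_noise(), meta = list(),
                           max_points = 20000L) {
  stopifnot(inherits(model, "consec_model"), inherits(noise, "noise_spec"),
            sampling_interval > 0)
  dur <- program_duration(program)
  n <- min(floor(dur / sampling_interval) + 1L, max_points)
  grid <- seq(0, dur, length.out = n)

  noisy <- !is.null(noise$seed)
  dT_off <- 0
  realised <- model
  draw <- function() stats::rnorm(1)
  if (noisy) {
    pert <- with_seed(noise$seed, {
      list(dT_off = stats::runif(1, -noise$temp_jitter_C, noise$temp_jitter_C),
           w_f = 1 + stats::rnorm(2) * noise$step_magnitude_rel_sigma,
           dm_f = 1 + stats::rnorm(1) * noise$total_loss_rel_sigma,
           mass_noise = stats::rnorm(n))
    })
    dT_off <- pert$dT_off
    w1 <- min(max(model$w1 * pert$w_f[1], 0), 1)
    w2 <- min(max(model$w2 * pert$w_f[2], 0), 1 - w1)
    dm <- sign(model$delta_m) * min(abs(model$delta_m * pert$dm_f), 1)
    realised <- consec_model(model$steps, w1 = w1, w2 = w2, delta_m = dm,
                             m_t0 = model$m_t0, seed_eps = model$seed_eps,
                             conversion = model$conversion)
  }

  tr <- integrate_model(realised, program, grid)
  m_pct <- 100 * tr$m
  T_C <- K_to_C(tr$T_K) + dT_off
  if (noisy) m_pct <- m_pct + 100 * noise$mass_sigma * pert$mass_noise
  m_pct <- pmin(pmax(m_pct, 1e-6), 120)

  truth <- list(
    E_J_mol = vapply(realised$steps, function(s)
      if (s$E$mode == "constant") s$E$E0 else NA_real_, numeric(1)),
    log10_A = vapply(realised$steps, function(s)
      log10(max(s$A, .Machine$double.xmin)), numeric(1)),
    M = vapply(realised$steps, `[[`, numeric(1), "M"),
    N = vapply(realised$steps, `[[`, numeric(1), "N"),
    w1 = realised$w1, w2 = realised$w2, delta_m = realised$delta_m,
    T_offset_C = dT_off, seed = noise$seed)
  tga_curve(tr$t, T_C, m_pct, meta = c(meta, list(truth = truth,
                                                  seed = noise$seed)))
}

#' Generate a full synthetic study
#'
#' One curve per (atmosphere, heating rate) combination, each from a fresh
#' per-curve seed split off the study seed. The returned object carries a
#' manifest recording, for every curve, its seed and realised generating
#' parameters, enabling closed-loop parameter-recovery tests.
#'
#' @param design a [study_design()].
#' @param noise a [noise_spec()]; its seed is the single master seed.
#' @return a `tga_study`: list with `curves` (list of [tga_curve()]) and
#'   `manifest` (data frame).
#' @export
generate_study <- function(design = study_design(), noise = no_noise()) {
  stopifnot(inherits(design, "study_design"))
  curves <- list()
  rows <- list()
  i <- 0L
  for (atm in names(design$atmosphere_models)) {
    model <- design$atmosphere_models[[atm]]
    for (q in design$q_list) {
      i <- i + 1L
      pr <- make_linear_ramp(C_to_K(design$T_span_C[1]),
                             C_to_K(design$T_span_C[2]), rate_to_K_s(q))
      cn <- if (!is.null(noise$seed)) {
        ns <- noise
        ns$seed <- split_seed(noise$seed, i)
        ns
      } else noise
      id <- sprintf("%s_q%s", atm, format(q, trim = TRUE))
      cur <- generate_curve(model, pr, design$sampling_interval, cn,
                            meta = list(sample_id = id, atmosphere = atm,
                                        q_plus_C_per_min = q,
                                        initial_mass_mg = 5),
                            max_points = design$max_points)
      curves[[id]] <- cur
      tr <- cur$meta$truth
      rows[[id]] <- data.frame(
        sample_id = id, atmosphere = atm, q_plus_C_per_min = q,
        seed = if (is.null(cn$seed)) NA_integer_ else cn$seed,
        E1 = tr$E_J_mol[1], E2 = tr$E_J_mol[2], E3 = tr$E_J_mol[3],
        log10_A1 = tr$log10_A[1], log10_A2 = tr$log10_A[2],
        log10_A3 = tr$log10_A[3],
        M1 = tr$M[1], M2 = tr$M[2], M3 = tr$M[3],
        N1 = tr$N[1], N2 = tr$N[2], N3 = tr$N[3],
        w1 = tr$w1, w2 = tr$w2, delta_m = tr$delta_m,
        T_offset_C = tr$T_offset_C, stringsAsFactors = FALSE)
    }
  }
  structure(list(curves = curves, manifest = do.call(rbind, c(rows, list(make.row.names = FALSE)))),
            class = "tga_study")
}

#' @export
print.tga_study <- function(x, ...) {
  cat("Synthetic TGA study:", length(x$curves), "curves\n")
  print(x$manifest[, c("sample_id", "atmosphere", "q_plus_C_per_min", "seed")])
  invisible(x)
}

#' Simulate mass-loss curves from a consecutive model
#'
#' `simulate()` method wrapping [generate_curve()]: draws `nsim` noisy
#' realisations of the model under a heating program.
#'
#' @param object a [consec_model()].
#' @param nsim number of curves.
#' @param seed master seed (split per realisation); `NULL` gives noiseless
#'   curves.
#' @param program a `heating_program` (default: 30-550 C scan at 10 C/min).
#' @param sampling_interval seconds between samples.
#' @param noise a [noise_spec()] template; its seed field is overridden by
#'   `seed`.
#' @param ... unused.
#' @return a list of [tga_curve()] objects.
#' @export
simulate.consec_model <- function(object, nsim = 1, seed = NULL,
                                  program = make_linear_ramp(C_to_K(30), C_to_K(550),
                                                             rate_to_K_s(10)),
                                  sampling_interval = 1,
                                  noise = noise_spec(seed = seed), ...) {
  if (is.null(seed)) noise <- no_noise()
  lapply(seq_len(nsim), function(i) {
    ns <- noise
    if (!is.null(seed)) ns$seed <- split_seed(seed, i)
    generate_curve(object, program, sampling_interval, ns,
                   meta = list(sample_id = paste0("sim_", i)))
  })
}
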