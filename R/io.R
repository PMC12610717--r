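#' Write a TGA curve to CSV (plus metadata sidecar)
#'
#' Deterministic formatting: fixed column order `time_s, temperature_C,
#' mass_pct`, ten significant digits, so identical curves produce
#' byte-identical files. Metadata, when present, is written to a sidecar
#' JSON with the same stem and suffix `.meta.json`.
#'
#' @param curve a [tga_curve()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "tga_curve"))
  lines <- c("time_s,temperature_C,mass_pct",
             sprintf("%.10g,%.10g,%.10g", curve$t, curve$T_C, curve$m_pct))
  writeLines(lines, path)
  meta <- curve$meta[intersect(names(curve$meta),
                               c("sample_id", "atmosphere", "q_plus_C_per_min",
                                 "initial_mass_mg", "seed"))]
  if (length(meta) > 0) {
    writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = I(17),
                                pretty = TRUE),
               sidecar_path(path))
  }
  invisible(path)
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".meta.json")

#' Read a TGA curve from CSV
#'
#' Expects the header `time_s,temperature_C,mass_pct` and validates the
#' curve invariants (sorted time, finite values, mass in (0, 120]),
#' reporting the offending row on failure. A sidecar `.meta.json` with the
#' same stem is read into the curve metadata when present.
#'
#' @param path CSV path.
#' @return a [tga_curve()].
#' @export
read_curve <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("time_s", "temperature_C", "mass_pct")
  if (!identical(names(df)[seq_along(need)], need))
    stop("malformed header: expected columns ", paste(need, collapse = ", "),
         call. = FALSE)
  for (col in need) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad) > 0)
      stop(sprintf("non-finite %s at row %d", col, bad[1]), call. = FALSE)
  }
  bad <- which(diff(df$time_s) <= 0)
  if (length(bad) > 0)
    stop("time not strictly increasing at row ", bad[1] + 1L, call. = FALSE)
  bad <- which(df$mass_pct <= 0 | df$mass_pct > 120)
  if (length(bad) > 0)
    stop("mass_pct outside (0, 120] at row ", bad[1], call. = FALSE)
  meta <- list()
  sp <- sidecar_path(path)
  if (file.exists(sp)) meta <- jsonlite::fromJSON(sp, simplifyVector = TRUE)
  tga_curve(df$time_s, df$temperature_C, df$mass_pct, meta = meta)
}

#' Write / read a synthetic study as a directory of curve CSVs
#'
#' `write_study()` writes one CSV (plus sidecar) per curve and a
#' `manifest.json` recording each curve's file, seed and realised generating
#' parameters; `read_study()` restores the curve list and manifest.
#'
#' @param study a `tga_study` from [generate_study()].
#' @param dir output directory (created if needed).
#' @return `write_study()` returns `dir` invisibly; `read_study()` a
#'   `tga_study`.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "tga_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(study$curves))
    write_curve(study$curves[[id]], file.path(dir, paste0(id, ".csv")))
  man <- study$manifest
  man$file <- paste0(man$sample_id, ".csv")
  writeLines(jsonlite::toJSON(man, dataframe = "rows", digits = I(17),
                              pretty = TRUE, na = "null"),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  mp <- file.path(dir, "manifest.json")
  if (!file.exists(mp)) stop("no manifest.json in ", dir, call. = FALSE)
  man <- jsonlite::fromJSON(mp)
  curves <- lapply(seq_len(nrow(man)), function(i)
    read_curve(file.path(dir, man$file[i])))
  names(curves) <- man$sample_id
  structure(list(curves = curves, manifest = man[names(man) != "file"]),
            class = "tga_study")
}

#' Serialise / read a Kissinger analysis
#'
#' JSON round trip of the peak table and per-step fits (linear E or
#' quadratic coefficients with validity window); the `lm` objects are not
#' retained.
#'
#' @param ka a `kissinger_analysis`.
#' @param path file path.
#' @return `read_kissinger()` returns a `kissinger_analysis`.
#' @export
write_kissinger <- function(ka, path) {
  stopifnot(inherits(ka, "kissinger_analysis"))
  fits <- lapply(ka$fits, function(f) {
    if (f$mode == "linear")
      list(mode = "linear", E = f$E, intercept = f$intercept,
           r_squared = f$r_squared, validity_window = f$validity_window)
    else
      list(mode = "quadratic", a = f$a, b = f$b, c = f$c,
           r_squared = f$r_squared, validity_window = f$validity_window)
  })
  doc <- list(n_steps = ka$n_steps, peaks = ka$peaks, fits = fits)
  writeLines(jsonlite::toJSON(doc, dataframe = "rows", auto_unbox = TRUE,
                              digits = I(17), pretty = TRUE), path)
  invisible(path)
}

#' @rdname write_kissinger
#' @export
read_kissinger <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  fits <- lapply(doc$fits, function(f) {
    f$validity_window <- as.numeric(f$validity_window)
    class(f) <- "kissinger_result"
    f
  })
  structure(list(peaks = doc$peaks, fits = fits, n_steps = doc$n_steps),
            class = "kissinger_analysis")
}
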