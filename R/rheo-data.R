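#' @keywords internal
"_PACKAGE"

# ---- validation helpers ------------------------------------------------

stop_validation <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

check_numeric_finite <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(x))))
    stop_validation("column '%s' contains non-numeric or non-finite values (row %s)",
                    name, paste(utils::head(bad, 3L), collapse = ", "))
  }
  invisible(x)
}

# ---- domain types ------------------------------------------------------

#' Frequency sweep at a single temperature
#'
#' The raw unit of all downstream computation: storage and loss moduli
#' `G'(omega)` and `G''(omega)` measured at one temperature in oscillatory
#' shear. Rows are normalized to strictly increasing angular frequency.
#'
#' @param omega angular frequency, rad/s, positive.
#' @param g_prime storage modulus, Pa, nonnegative.
#' @param g_double_prime loss modulus, Pa, nonnegative.
#' @param temperature test temperature, degrees C.
#' @param mode `"CS"` (controlled stress, amplitude in Pa) or `"CD"`
#'   (controlled deformation, amplitude a dimensionless strain).
#' @param amplitude oscillation amplitude in the unit implied by `mode`.
#' @param gap plate gap, mm.
#' @param sample_id free-text sample label.
#' @return An object of class `frequency_sweep`: a list with the validated,
#'   ascending-frequency arrays and metadata fields.
#' @export
frequency_sweep <- function(omega, g_prime, g_double_prime,
                            temperature, mode = c("CS", "CD"),
                            amplitude = NA_real_, gap = NA_real_,
                            sample_id = "") {
  mode <- match.arg(mode)
  check_numeric_finite(omega, "omega_rad_per_s")
  check_numeric_finite(g_prime, "g_prime_pa")
  check_numeric_finite(g_double_prime, "g_double_prime_pa")
  n <- length(omega)
  if (n < 3L || length(g_prime) != n || length(g_double_prime) != n)
    stop_validation("frequency sweep needs >= 3 rows with equal-length columns (got %d)", n)
  if (any(omega <= 0))
    stop_validation("omega must be positive (row %d)", which(omega <= 0)[1L])
  if (any(g_prime < 0))
    stop_validation("negative storage modulus (row %d, column g_prime_pa)",
                    which(g_prime < 0)[1L])
  if (any(g_double_prime < 0))
    stop_validation("negative loss modulus (row %d, column g_double_prime_pa)",
                    which(g_double_prime < 0)[1L])
  if (!is.finite(temperature))
    stop_validation("temperature must be finite")
  ord <- order(omega)
  if (anyDuplicated(omega))
    stop_validation("duplicated omega values (row %d)", anyDuplicated(omega))
  structure(list(
    omega = as.numeric(omega[ord]),
    g_prime = as.numeric(g_prime[ord]),
    g_double_prime = as.numeric(g_double_prime[ord]),
    temperature = as.numeric(temperature),
    mode = mode, amplitude = as.numeric(amplitude),
    gap = as.numeric(gap), sample_id = as.character(sample_id)
  ), class = "frequency_sweep")
}

#' Amplitude (stress or strain) sweep at fixed frequency and temperature
#'
#' @param amplitude oscillation amplitude (Pa for CS, dimensionless for CD),
#'   positive, normalized to increasing order.
#' @param g_prime,g_double_prime moduli, Pa.
#' @param temperature degrees C.
#' @param fixed_omega test angular frequency, rad/s.
#' @param mode `"CS"` or `"CD"` (disambiguates the amplitude unit).
#' @return An object of class `amplitude_sweep`.
#' @export
amplitude_sweep <- function(amplitude, g_prime, g_double_prime,
                            temperature, fixed_omega,
                            mode = c("CS", "CD")) {
  mode <- match.arg(mode)
  check_numeric_finite(amplitude, "amplitude")
  check_numeric_finite(g_prime, "g_prime_pa")
  check_numeric_finite(g_double_prime, "g_double_prime_pa")
  n <- length(amplitude)
  if (n < 3L || length(g_prime) != n || length(g_double_prime) != n)
    stop_validation("amplitude sweep needs >= 3 rows with equal-length columns (got %d)", n)
  if (any(amplitude <= 0))
    stop_validation("amplitudes must be positive (row %d)", which(amplitude <= 0)[1L])
  if (any(g_prime < 0))
    stop_validation("negative storage modulus (row %d, column g_prime_pa)",
                    which(g_prime < 0)[1L])
  if (any(g_double_prime < 0))
    stop_validation("negative loss modulus (row %d, column g_double_prime_pa)",
                    which(g_double_prime < 0)[1L])
  ord <- order(amplitude)
  structure(list(
    amplitude = as.numeric(amplitude[ord]),
    g_prime = as.numeric(g_prime[ord]),
    g_double_prime = as.numeric(g_double_prime[ord]),
    temperature = as.numeric(temperature),
    fixed_omega = as.numeric(fixed_omega), mode = mode
  ), class = "amplitude_sweep")
}

#' Temperature sweep: complex viscosity and loss tangent vs temperature
#'
#' Used to locate the denaturation temperature either from the ~50% drop of
#' the viscosity or from the maximum of tan(delta) = G''/G'.
#'
#' @param temperature degrees C, normalized to increasing order.
#' @param viscosity complex viscosity, Pa s, positive.
#' @param tan_delta loss tangent, dimensionless, positive.
#' @return An object of class `temperature_sweep`.
#' @export
temperature_sweep <- function(temperature, viscosity, tan_delta) {
  check_numeric_finite(temperature, "temperature_c")
  check_numeric_finite(viscosity, "viscosity_pa_s")
  check_numeric_finite(tan_delta, "tan_delta")
  n <- length(temperature)
  if (n < 3L || length(viscosity) != n || length(tan_delta) != n)
    stop_validation("temperature sweep needs >= 3 rows with equal-length columns (got %d)", n)
  if (any(viscosity <= 0))
    stop_validation("viscosity must be positive (row %d, column viscosity_pa_s)",
                    which(viscosity <= 0)[1L])
  if (any(tan_delta <= 0))
    stop_validation("tan_delta must be positive (row %d, column tan_delta)",
                    which(tan_delta <= 0)[1L])
  ord <- order(temperature)
  structure(list(
    temperature = as.numeric(temperature[ord]),
    viscosity = as.numeric(viscosity[ord]),
    tan_delta = as.numeric(tan_delta[ord])
  ), class = "temperature_sweep")
}

#' Stress-relaxation curve G(t)
#'
#' @param time time, s, strictly increasing, positive.
#' @param modulus relaxation modulus, Pa.
#' @return An object of class `relaxation_curve`.
#' @export
relaxation_curve <- function(time, modulus) {
  check_numeric_finite(time, "time_s")
  check_numeric_finite(modulus, "modulus_pa")
  if (length(time) != length(modulus))
    stop_validation("time and modulus must have equal length")
  if (any(time <= 0)) stop_validation("time must be positive")
  ord <- order(time)
  structure(list(time = as.numeric(time[ord]),
                 modulus = as.numeric(modulus[ord])),
            class = "relaxation_curve")
}

#' Pipeline run configuration
#'
#' Collects every tunable of the sweep-to-MWD pipeline in one object that can
#' round-trip through a JSON file (`read_run_config()` / `write_result()`).
#'
#' @param lve_tolerance relative tolerance of the LVE plateau criterion.
#' @param td_drop_fraction fractional viscosity drop defining Td.
#' @param lambda_grid list `(min, max, points_per_decade)` for the relaxation
#'   time grid, s.
#' @param mass_grid list `(min, max, points_per_decade)` for the molar-mass
#'   grid, g/mol.
#' @param regularization list `(method, strengths)`: candidate curvature
#'   penalty strengths scanned by the L-curve.
#' @param reptation a [reptation_params()] object.
#' @param tts list `(reference_temperature, vertical)`.
#' @param seed integer seed for any stochastic stage.
#' @return An object of class `run_config`.
#' @export
run_config <- function(lve_tolerance = 0.05,
                       td_drop_fraction = 0.5,
                       lambda_grid = list(min = 1e-4, max = 1e4, points_per_decade = 10),
                       mass_grid = list(min = 1e4, max = 1e8, points_per_decade = 10),
                       regularization = list(method = "curvature_nnls",
                                             strengths = 10^seq(-6, 2, by = 0.5)),
                       reptation = reptation_params(),
                       tts = list(reference_temperature = NA_real_, vertical = FALSE),
                       seed = 1L) {
  for (g in list(lambda_grid, mass_grid)) {
    if (!(g$min > 0 && g$max > g$min && g$points_per_decade >= 1))
      stop_validation("grids must have 0 < min < max and >= 1 point per decade")
  }
  if (!(lve_tolerance > 0 && lve_tolerance < 1))
    stop_validation("lve_tolerance must lie in (0,1)")
  if (!(td_drop_fraction > 0 && td_drop_fraction < 1))
    stop_validation("td_drop_fraction must lie in (0,1)")
  structure(list(lve_tolerance = lve_tolerance,
                 td_drop_fraction = td_drop_fraction,
                 lambda_grid = lambda_grid, mass_grid = mass_grid,
                 regularization = regularization, reptation = reptation,
                 tts = tts, seed = as.integer(seed)),
            class = "run_config")
}

# ---- readers -----------------------------------------------------------

sidecar_path <- function(path) sub("\\.[^.]+$", "", path) |> paste0(".meta.json")

read_sidecar <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) return(NULL)
  jsonlite::read_json(sc, simplifyVector = TRUE)
}

#' Read a sweep table from a delimited text file
#'
#' Files are comma-separated with one header row and a `.` decimal; metadata
#' (temperature, mode, amplitude, gap, sample id) lives in a JSON sidecar
#' `<name>.meta.json` next to the table. Expected columns:
#' \describe{
#'   \item{frequency}{`omega_rad_per_s, g_prime_pa, g_double_prime_pa`
#'     (a `frequency_hz` column is accepted instead of `omega_rad_per_s`
#'     and converted by `omega = 2*pi*f`, with a message)}
#'   \item{amplitude}{`amplitude, g_prime_pa, g_double_prime_pa`}
#'   \item{temperature}{`temperature_c, viscosity_pa_s, tan_delta`}
#' }
#' Rows are reordered to increasing abscissa; all type invariants are
#' validated on read with errors naming the offending row and column.
#'
#' @param path path to the CSV table.
#' @param kind one of `"frequency"`, `"amplitude"`, `"temperature"`.
#' @return A [frequency_sweep()], [amplitude_sweep()] or
#'   [temperature_sweep()] object.
#' @export
read_sweep <- function(path, kind = c("frequency", "amplitude", "temperature")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) < 3L) stop_validation("fewer than 3 data rows in %s", path)
  meta <- read_sidecar(path)
  need <- function(cols) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop_validation("missing column(s) %s in %s", paste(miss, collapse = ", "), path)
  }
  getmeta <- function(key, default = NA_real_) {
    if (!is.null(meta) && !is.null(meta[[key]])) meta[[key]] else default
  }
  switch(kind,
    frequency = {
      if ("frequency_hz" %in% names(df) && !"omega_rad_per_s" %in% names(df)) {
        message("converting frequency_hz to omega_rad_per_s via omega = 2*pi*f")
        df$omega_rad_per_s <- 2 * pi * df$frequency_hz
      }
      need(c("omega_rad_per_s", "g_prime_pa", "g_double_prime_pa"))
      frequency_sweep(df$omega_rad_per_s, df$g_prime_pa, df$g_double_prime_pa,
                      temperature = getmeta("temperature_c"),
                      mode = as.character(getmeta("mode", "CS")),
                      amplitude = getmeta("amplitude"),
                      gap = getmeta("gap_mm"),
                      sample_id = as.character(getmeta("sample_id", "")))
    },
    amplitude = {
      need(c("amplitude", "g_prime_pa", "g_double_prime_pa"))
      amplitude_sweep(df$amplitude, df$g_prime_pa, df$g_double_prime_pa,
                      temperature = getmeta("temperature_c"),
                      fixed_omega = getmeta("fixed_omega_rad_per_s"),
                      mode = as.character(getmeta("mode", "CS")))
    },
    temperature = {
      need(c("temperature_c", "viscosity_pa_s", "tan_delta"))
      temperature_sweep(df$temperature_c, df$viscosity_pa_s, df$tan_delta)
    }
  )
}

#' Read a pipeline configuration from JSON
#'
#' @param path path to a JSON file with [run_config()] fields; missing fields
#'   take their defaults.
#' @return A [run_config()] object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_validation("config not found: %s", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- run_config()
  if (!is.null(x$reptation))
    x$reptation <- do.call(reptation_params, x$reptation[
      intersect(names(x$reptation), c("G_N", "Me", "beta", "K", "alpha"))])
  for (nm in names(defaults)) if (is.null(x[[nm]])) x[[nm]] <- defaults[[nm]]
  do.call(run_config, x[names(defaults)])
}

# ---- writers -----------------------------------------------------------

assert_finite_payload <- function(x) {
  vals <- unlist(x[vapply(x, is.numeric, logical(1L))], use.names = FALSE)
  if (anyNA(vals) || any(!is.finite(vals)))
    stop_validation("result contains NaN/Inf/NA; refusing to write")
  invisible(TRUE)
}

write_table_15 <- function(df, path) {
  df[] <- lapply(df, function(col)
    if (is.numeric(col)) formatC(col, digits = 15, format = "g") else col)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Write a result object to disk
#'
#' Numeric tables are written as CSV with 15 significant digits so that a
#' read/write round trip preserves values to at least 12 significant digits;
#' scalar summaries accompany the table as `<name>.summary.json`.
#'
#' @param x a result object (`mw_distribution`, `continuous_spectrum`,
#'   `master_curve`, `relaxation_curve`, `frequency_sweep`, or `run_config`).
#' @param path output path (CSV for tables, JSON for configs).
#' @return `path`, invisibly.
#' @export
write_result <- function(x, path) UseMethod("write_result")

#' @export
write_result.mw_distribution <- function(x, path) {
  assert_finite_payload(x)
  write_table_15(data.frame(mass_g_per_mol = x$mass_grid, w = x$w), path)
  jsonlite::write_json(
    list(Mw = x$Mw, Mn = x$Mn, PDI = x$PDI, components = x$components),
    sub("\\.csv$", "", path) |> paste0(".summary.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
write_result.continuous_spectrum <- function(x, path) {
  assert_finite_payload(x[c("lambda_grid", "H")])
  write_table_15(data.frame(lambda_s = x$lambda_grid, H_pa = x$H), path)
  invisible(path)
}

#' @export
write_result.master_curve <- function(x, path) {
  assert_finite_payload(x[c("omega", "g_prime", "g_double_prime")])
  write_table_15(data.frame(
    omega_rad_per_s = x$omega, g_prime_pa = x$g_prime,
    g_double_prime_pa = x$g_double_prime,
    source_temperature_c = x$source_temperature_per_point), path)
  invisible(path)
}

#' @export
write_result.relaxation_curve <- function(x, path) {
  assert_finite_payload(x)
  write_table_15(data.frame(time_s = x$time, modulus_pa = x$modulus), path)
  invisible(path)
}

#' @export
write_result.frequency_sweep <- function(x, path) {
  assert_finite_payload(x[c("omega", "g_prime", "g_double_prime")])
  write_table_15(data.frame(omega_rad_per_s = x$omega, g_prime_pa = x$g_prime,
                            g_double_prime_pa = x$g_double_prime), path)
  jsonlite::write_json(
    list(temperature_c = x$temperature, mode = x$mode, amplitude = x$amplitude,
         gap_mm = x$gap, sample_id = x$sample_id),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
write_result.run_config <- function(x, path) {
  x <- unclass(x)
  x$reptation <- unclass(x$reptation)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read back a previously written result table
#'
#' Inverse of [write_result()] for the tabular result types.
#'
#' @param path CSV written by [write_result()].
#' @param kind one of `"mwd"`, `"spectrum"`, `"master"`, `"relaxation"`.
#' @return The reconstructed result object.
#' @export
read_result <- function(path, kind = c("mwd", "spectrum", "master", "relaxation")) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path)
  switch(kind,
    mwd = {
      sm <- jsonlite::read_json(sub("\\.csv$", "", path) |> paste0(".summary.json"),
                                simplifyVector = TRUE)
      structure(list(mass_grid = df$mass_g_per_mol, w = df$w,
                     Mw = sm$Mw, Mn = sm$Mn, PDI = sm$PDI,
                     components = sm$components),
                class = "mw_distribution")
    },
    spectrum = continuous_spectrum(df$lambda_s, df$H_pa),
    master = structure(list(
      omega = df$omega_rad_per_s, g_prime = df$g_prime_pa,
      g_double_prime = df$g_double_prime_pa,
      source_temperature_per_point = df$source_temperature_c,
      reference_temperature = NA_real_), class = "master_curve"),
    relaxation = relaxation_curve(df$time_s, df$modulus_pa)
  )
}

#' @export
print.frequency_sweep <- function(x, ...) {
  cat(sprintf("<frequency_sweep> %d points, %.3g-%.3g rad/s, T = %.1f C, mode %s\n",
              length(x$omega), min(x$omega), max(x$omega), x$temperature, x$mode))
  invisible(x)
}
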