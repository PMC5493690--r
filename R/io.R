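# Full-precision CSV writer: numbers serialised with 17 significant digits so
# that read -> write -> read round-trips bit-identical doubles.
.write_precise_csv <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]))
      out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
}

.sweep_columns <- c("omega_x_hz", "omega_z_hz", "temperature_k", "transition",
                    "gamma_per_s", "inverse_s", "gamma_elastic_per_s",
                    "ratio_to_elastic", "flags")

#' Write sweep results
#'
#' Serialises a [run_sweep()] table as CSV (header row, stable column order,
#' full-precision scientific notation) or as a JSON array of records.
#' Reading the file back with [read_results()] reproduces the table exactly.
#'
#' @param result A non-empty `sweep_result` data frame.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`; default guessed from the file
#'   extension.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(result))
  if (!nrow(result)) stop("refusing to write an empty result table")
  if (!all(.sweep_columns %in% names(result)))
    stop("result is missing sweep columns: ",
         paste(setdiff(.sweep_columns, names(result)), collapse = ", "))
  result <- result[, .sweep_columns]
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "csv") {
    .write_precise_csv(result, path)
  } else {
    # I(17) = 17 *significant* digits: exact double round-trip
    jsonlite::write_json(result, path, dataframe = "rows", digits = I(17),
                         na = "null", auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read sweep results
#'
#' @param path File written by [write_results()].
#' @param format `"csv"`, `"json"`, or `"auto"` (extension-based).
#' @return A `sweep_result` data frame.
#' @export
read_results <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  df <- if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
  if ("flags" %in% names(df)) {
    df$flags[is.na(df$flags)] <- ""
    df$flags <- as.character(df$flags)
  }
  num <- setdiff(.sweep_columns, c("transition", "flags"))
  for (nm in intersect(num, names(df))) df[[nm]] <- as.numeric(df[[nm]])
  class(df) <- c("sweep_result", "data.frame")
  df
}

#' Read a flat parameter configuration
#'
#' Parameter sets travel as flat key-value YAML or JSON files with
#' SI-suffixed keys.  Recognised keys: `omega_x_hz`, `omega_z_hz`, `eps_hz`,
#' `delta_hz`, `gamma_d_hz`, `gamma_a_hz`, `temperature_k`, and the bath block
#' `form`, `coupling`, `cutoff_hz`.  Missing electronic keys fall back to the
#' odorant-consistent defaults; missing bath keys to the aqueous bath.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `odorant`, `params`, `spectrum`, `state`
#'   ready to feed [rate_request()], plus the raw key-value list as `raw`.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$omega_x_hz) || is.null(raw$omega_z_hz))
    stop("config must supply omega_x_hz and omega_z_hz")
  od <- odorant_two_level(as.numeric(raw$omega_x_hz),
                          as.numeric(raw$omega_z_hz), warn = FALSE)
  params <- default_electronic_parameters(od)
  if (!is.null(raw$eps_hz)) params$eps <- as.numeric(raw$eps_hz)
  if (!is.null(raw$delta_hz)) params$delta <- as.numeric(raw$delta_hz)
  if (!is.null(raw$gamma_d_hz)) params$gamma_D <- as.numeric(raw$gamma_d_hz)
  if (!is.null(raw$gamma_a_hz)) params$gamma_A <- as.numeric(raw$gamma_a_hz)
  spectrum <- bath_spectrum(
    form = if (is.null(raw$form)) "ohmic_exponential" else raw$form,
    coupling = if (is.null(raw$coupling)) 1 else as.numeric(raw$coupling),
    cutoff = if (is.null(raw$cutoff_hz)) 1e12 else as.numeric(raw$cutoff_hz))
  state <- thermal_state(
    if (is.null(raw$temperature_k)) 310 else as.numeric(raw$temperature_k))
  list(odorant = od, params = params, spectrum = spectrum, state = state,
       raw = raw)
}

#' Write a flat parameter configuration
#'
#' Inverse of [read_config()]: serialises a rate request's parameters into
#' the flat SI-keyed dialect.
#'
#' @param req A [rate_request()].
#' @param path Output path; extension selects YAML (default) or JSON.
#' @return `path`, invisibly.
#' @export
write_config <- function(req, path) {
  stopifnot(inherits(req, "rate_request"))
  kv <- list(omega_x_hz = req$odorant$omega_x, omega_z_hz = req$odorant$omega_z,
             eps_hz = req$params$eps, delta_hz = req$params$delta,
             gamma_d_hz = req$params$gamma_D, gamma_a_hz = req$params$gamma_A,
             temperature_k = req$state$temperature,
             form = req$spectrum$form, coupling = req$spectrum$coupling,
             cutoff_hz = req$spectrum$cutoff)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(kv, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(kv, path)
  }
  invisible(path)
}
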