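# Raw-signal container, event tables, calibration tables, configuration.
#
# The raw container (.ebs) is a self-describing binary file: an 8-byte
# magic string, a 4-byte little-endian header length, a JSON header with
# the attributes sample_rate_hz / start_time_utc / acquisition_range_mv /
# label / dtype / n_samples / raw, then the samples. dtype "uint16" stores
# 16-bit digitizer codes (mV = code * range / 2^16) and round-trips them
# bit-exactly; dtype "double" stores millivolts as IEEE doubles.

.ebs_magic <- "EBSSIG1\n"

.time_to_iso <- function(t) format(t, "%Y-%m-%dT%H:%M:%OS6", tz = "UTC", usetz = FALSE)
.time_from_iso <- function(s) {
  t <- as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  bad <- which(is.na(t))
  if (length(bad))
    stop("format error: unparseable 'start_time_utc' value: ", s[bad[1]])
  t
}

#' Write a signal record to a self-describing container file
#'
#' @param record a [signal_record()].
#' @param path output file path (conventionally `.ebs`).
#' @param dtype `"double"` stores millivolts as 64-bit floats; `"uint16"`
#'   stores 16-bit digitizer codes (`code = round(mv * 2^16 / range)`),
#'   which round-trip bit-exactly and quarter the file size.
#' @param overwrite must be `TRUE` to replace an existing file.
#' @return `path`, invisibly.
#' @seealso [read_signal()]
#' @export
write_signal <- function(record, path, dtype = c("double", "uint16"),
                         overwrite = FALSE) {
  stopifnot(inherits(record, "signal_record"))
  dtype <- match.arg(dtype)
  if (file.exists(path) && !isTRUE(overwrite))
    stop("write_signal: '", path, "' exists; pass overwrite = TRUE to replace")
  header <- list(
    format = "ebossflux-signal", version = 1L,
    sample_rate_hz = record$sample_rate,
    start_time_utc = .time_to_iso(record$start_time),
    acquisition_range_mv = record$acquisition_range_mv,
    label = record$label, raw = record$raw,
    dtype = dtype, n_samples = length(record$samples))
  hjson <- charToRaw(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw(.ebs_magic), con)
  writeBin(length(hjson), con, size = 4L, endian = "little")
  writeBin(hjson, con)
  if (dtype == "uint16") {
    codes <- as.integer(round(record$samples * 65536 /
                                record$acquisition_range_mv))
    if (any(codes < 0L | codes > 65535L))
      stop("write_signal: samples outside the acquisition range cannot be ",
           "stored as uint16 codes")
    writeBin(codes, con, size = 2L, endian = "little")
  } else {
    writeBin(record$samples, con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' Read a signal record from a container file
#'
#' @param path file written by [write_signal()].
#' @return A [signal_record()]. Integer-coded files are converted back to
#'   millivolts as `code * range / 2^16`.
#' @export
read_signal <- function(path) {
  if (!file.exists(path)) stop("read_signal: no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- rawToChar(readBin(con, "raw", n = nchar(.ebs_magic)))
  if (!identical(magic, .ebs_magic))
    stop("format error: '", path, "' is not an ebossflux signal container")
  hlen <- readBin(con, "integer", size = 4L, endian = "little")
  if (length(hlen) != 1L || is.na(hlen) || hlen <= 0L)
    stop("format error: corrupt header length")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", n = hlen)))
  for (field in c("sample_rate_hz", "start_time_utc", "acquisition_range_mv",
                  "dtype", "n_samples")) {
    if (is.null(header[[field]]))
      stop("format error: container lacks required field '", field, "'")
  }
  n <- as.integer(header$n_samples)
  samples <- switch(
    header$dtype,
    uint16 = readBin(con, "integer", n = n, size = 2L, signed = FALSE,
                     endian = "little") *
      header$acquisition_range_mv / 65536,
    double = readBin(con, "double", n = n, size = 8L, endian = "little"),
    stop("format error: unknown dtype '", header$dtype, "'"))
  if (length(samples) != n)
    stop("format error: truncated payload (expected ", n, " samples, got ",
         length(samples), ")")
  signal_record(samples, header$sample_rate_hz,
                .time_from_iso(header$start_time_utc),
                label = if (is.null(header$label)) "" else header$label,
                acquisition_range_mv = header$acquisition_range_mv,
                raw = isTRUE(header$raw))
}

#' Read a mass-calibration table
#'
#' A calibration table holds one row per weighed specimen: a group label,
#' the body extinction cross section measured on a laboratory sensor, and
#' the wet and dry masses from a precision scale.
#'
#' @param path CSV with columns `group, sigma_mm2, mass_wet_mg, mass_dry_mg`.
#' @return A `data.frame` with those columns, validated (positive cross
#'   sections and masses, dry <= wet).
#' @export
read_calibration_table <- function(path) {
  if (!file.exists(path)) stop("read_calibration_table: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "sigma_mm2", "mass_wet_mg", "mass_dry_mg")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_calibration_table: missing column(s): ",
         paste(miss, collapse = ", "))
  validate_calibration(df)
  df[need]
}

validate_calibration <- function(df) {
  bad <- which(!is.finite(df$sigma_mm2) | df$sigma_mm2 <= 0)
  if (length(bad))
    stop("calibration row ", bad[1], ": extinction cross section must be > 0")
  bad <- which(!is.finite(df$mass_wet_mg) | df$mass_wet_mg <= 0 |
                 !is.finite(df$mass_dry_mg) | df$mass_dry_mg <= 0)
  if (length(bad))
    stop("calibration row ", bad[1], ": masses must be > 0")
  bad <- which(df$mass_dry_mg > df$mass_wet_mg)
  if (length(bad))
    stop("calibration row ", bad[1],
         ": dry mass exceeds wet mass (physically impossible)")
  invisible(df)
}

#' @rdname read_calibration_table
#' @param df calibration `data.frame` to write.
#' @export
write_calibration_table <- function(df, path) {
  validate_calibration(df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

.event_table_cols <- c("event_id", "start_time_utc", "transit_time_s",
                       "i0_mv", "ib_mv", "sigma_b_mm2", "wingbeat_hz",
                       "kurtosis", "mass_wet_mg", "mass_dry_mg", "is_insect")

#' Read or write an event table
#'
#' Event tables use a fixed CSV header:
#' `event_id,start_time_utc,transit_time_s,i0_mv,ib_mv,sigma_b_mm2,`
#' `wingbeat_hz,kurtosis,mass_wet_mg,mass_dry_mg,is_insect`.
#'
#' @param events event `data.frame` as produced by [run_pipeline()].
#' @param path CSV file path.
#' @return The event `data.frame` (read) or `path` invisibly (write).
#' @export
write_event_table <- function(events, path) {
  miss <- setdiff(.event_table_cols, names(events))
  if (length(miss))
    stop("write_event_table: missing column(s): ", paste(miss, collapse = ", "))
  out <- events[.event_table_cols]
  out$start_time_utc <- .time_to_iso(out$start_time_utc)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.event_table_cols, names(df))
  if (length(miss))
    stop("read_event_table: missing column(s): ", paste(miss, collapse = ", "))
  df$start_time_utc <- .time_from_iso(df$start_time_utc)
  df$is_insect <- as.logical(df$is_insect)
  df[.event_table_cols]
}

# --- configuration (flat TOML subset: key = value, one [geometry] table) ---

.toml_scalar <- function(v) {
  if (is.character(v)) sprintf('"%s"', v)
  else if (is.logical(v)) tolower(as.character(v))
  else format(v, digits = 15, scientific = FALSE)
}

#' Read or write the run configuration
#'
#' The configuration file is TOML (restricted to `key = value` pairs plus a
#' `[geometry]` table) with keys mirroring [run_config()]; absent keys keep
#' their defaults.
#'
#' @param config a [run_config()].
#' @param path TOML file path.
#' @return A [run_config()] (read) or `path` invisibly (write).
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  scalars <- config[setdiff(names(config), c("geometry", "seed"))]
  lines <- c("# ebossflux run configuration",
             vapply(names(scalars), function(k)
               sprintf("%s = %s", k, .toml_scalar(scalars[[k]])), ""),
             if (!is.null(config$seed)) sprintf("seed = %d", config$seed),
             "", "[geometry]",
             sprintf("beam_diameter_m = %s",
                     .toml_scalar(config$geometry$beam_diameter_m)),
             sprintf("path_length_m = %s",
                     .toml_scalar(config$geometry$path_length_m)))
  writeLines(lines, path)
  invisible(path)
}

.parse_toml_value <- function(s) {
  s <- trimws(s)
  if (grepl('^".*"$', s)) return(gsub('^"|"$', "", s))
  if (s %in% c("true", "false")) return(s == "true")
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v)) stop("config parse error: bad value '", s, "'")
  v
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("read_run_config: no such file: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- ""
  top <- list(); geom <- list()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    kv <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(kv) != 3L) stop("config parse error: bad line '", ln, "'")
    val <- .parse_toml_value(kv[3])
    if (section == "geometry") geom[[kv[2]]] <- val
    else if (section == "") top[[kv[2]]] <- val
    else stop("config parse error: unknown table [", section, "]")
  }
  geometry <- do.call(probe_geometry, geom[intersect(
    names(geom), c("beam_diameter_m", "path_length_m"))])
  args <- top[intersect(names(top), setdiff(names(formals(run_config)),
                                            "geometry"))]
  args$n_harmonics <- if (!is.null(args$n_harmonics))
    as.integer(args$n_harmonics)
  args$geometry <- geometry
  do.call(run_config, args[!vapply(args, is.null, TRUE)])
}
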