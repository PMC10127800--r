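## Recording CSV dialect (v1):
##   '#'-prefixed metadata header of "key: value" lines (scalar entries; the
##   generating parameter vector is flattened to "param.<name>" keys),
##   then a "time_s,da_um" table. Values are written at full double precision
##   so a write -> read round trip is exact to the printed 17 significant
##   digits.

#' Write a recording to CSV
#'
#' @param rec an [fscv_recording()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "fscv_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# fscv_recording v1", con)
  md <- rec$metadata
  for (nm in names(md)) {
    v <- md[[nm]]
    if (nm == "params") {
      for (pn in names(v))
        writeLines(sprintf("# param.%s: %.17g", pn, v[[pn]]), con)
    } else if (length(v) == 1L) {
      writeLines(sprintf("# %s: %s", nm,
                         if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)),
                 con)
    }
  }
  writeLines("time_s,da_um", con)
  writeLines(sprintf("%.17g,%.17g", rec$time, rec$da), con)
  invisible(path)
}

#' Read a recording from CSV
#'
#' Parses the dialect written by [write_recording()]. A missing metadata
#' header yields an empty-metadata recording with a warning; a malformed
#' table, non-monotone time or non-finite value is an error naming the
#' offending row.
#'
#' @param path input file
#' @return an [fscv_recording()]
#' @export
read_recording <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta_lines <- lines[is_meta]
  body <- lines[!is_meta]
  metadata <- list()
  if (!length(meta_lines)) {
    warning("read_recording: no metadata header in ", path,
            "; recording loaded with empty metadata")
  } else {
    kv <- meta_lines[grepl(":", meta_lines, fixed = TRUE)]
    kv <- kv[!grepl("^#\\s*fscv_recording", kv)]
    params <- numeric(0)
    for (line in kv) {
      m <- regmatches(line, regexec("^#\\s*([^:]+):\\s*(.*)$", line))[[1L]]
      key <- trimws(m[2L]); val <- trimws(m[3L])
      num <- suppressWarnings(as.numeric(val))
      if (startsWith(key, "param.")) {
        params[sub("^param\\.", "", key)] <- num
      } else {
        metadata[[key]] <- if (!is.na(num)) num else val
      }
    }
    if (length(params)) metadata$params <- params
  }
  if (!length(body) || body[1L] != "time_s,da_um")
    stop("read_recording: malformed header, expected 'time_s,da_um' in ", path)
  rows <- body[-1L]
  if (!length(rows)) stop("read_recording: no data rows in ", path)
  parts <- strsplit(rows, ",", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("read_recording: malformed data row ",
         which(lengths(parts) != 2L)[1L], " in ", path)
  time <- as.numeric(vapply(parts, `[[`, character(1), 1L))
  da <- as.numeric(vapply(parts, `[[`, character(1), 2L))
  if (any(!is.finite(time)) || any(!is.finite(da)))
    stop("read_recording: non-finite value at data row ",
         which(!is.finite(time) | !is.finite(da))[1L], " in ", path)
  if (length(time) > 1L && any(diff(time) <= 0))
    stop("read_recording: time not strictly increasing at data row ",
         which(diff(time) <= 0)[1L] + 1L, " in ", path)
  fscv_recording(time, da, metadata)
}

#' Write a simulated concentration trace to CSV
#'
#' Plain table `time_s,da_s_um,da_e_um,gamma_um` of all three model states.
#'
#' @param trace a `conc_trace` from [simulate_trace()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "conc_trace"))
  df <- data.frame(time_s = trace$time, da_s_um = trace$DA_S,
                   da_e_um = trace$DA_E, gamma_um = trace$Gamma_DA)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

## --- configuration -------------------------------------------------------

.protocol_keys <- c("n_pulses", "frequency_hz", "current_ma", "onset_s",
                    "n_bursts", "inter_burst_interval_s")

protocol_from_list <- function(x) {
  unknown <- setdiff(names(x), .protocol_keys)
  if (length(unknown))
    stop("config: unknown protocol key(s): ", paste(unknown, collapse = ", "))
  do.call(stim_protocol, x)
}

params_from_list <- function(x) {
  unknown <- setdiff(names(x), c(.param_fields, "free"))
  if (length(unknown))
    stop("config: unknown parameter key(s): ", paste(unknown, collapse = ", "))
  do.call(kinetic_params, x)
}

#' Read a model configuration file
#'
#' A flat YAML (or JSON) file with two blocks: `protocol` (`n_pulses`,
#' `frequency_hz`, `current_ma`, `onset_s`, optional multi-burst fields) and
#' `parameters` (the ten kinetic parameters plus a `free` list). Unknown keys
#' — including unit suffixes the package does not use — are an error rather
#' than being converted silently.
#'
#' @param path YAML or JSON file
#' @return a list with elements `protocol` ([stim_protocol()]) and
#'   `parameters` ([kinetic_params()])
#' @export
read_model_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), c("protocol", "parameters"))
  if (length(unknown))
    stop("config: unknown block(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$protocol) || is.null(cfg$parameters))
    stop("config: both 'protocol' and 'parameters' blocks are required")
  list(protocol = protocol_from_list(cfg$protocol),
       parameters = params_from_list(cfg$parameters))
}
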