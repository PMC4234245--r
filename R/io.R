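#' Read an experiment configuration file
#'
#' Configuration files are plain text, either YAML (when the `yaml`
#' package is installed) or JSON. Fields mirror the arguments of
#' [experiment_config()].
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return an `experiment_config`.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for YAML configs; use JSON")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(vals$experiment)) stop("config must name an 'experiment'")
  args <- vals[setdiff(names(vals), c("experiment", "profile"))]
  do.call(experiment_config,
          c(list(experiment = vals$experiment,
                 profile = if (is.null(vals$profile)) "ci" else vals$profile),
            args))
}

#' Export a single EGM trace as two-column CSV
#' @param trace an `egm_trace`.
#' @param path output path; columns `time_ms`, `amplitude`.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "egm_trace"))
  write.csv(data.frame(time_ms = trace$t, amplitude = trace$samples),
            path, row.names = FALSE)
}

#' Export a Shannon entropy map as delimited text plus a JSON sidecar
#'
#' The matrix is written as tab-separated values; the sidecar records
#' the histogram specification, analysis window and map statistics.
#'
#' @param map a `shen_map`.
#' @param path output path for the matrix; the sidecar gets `.json`
#'   appended.
#' @export
write_map_txt <- function(map, path) {
  stopifnot(inherits(map, "shen_map"))
  utils::write.table(map$values, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(histogram = unclass(map$histogram_spec),
               window = map$window, spacing = map$spacing,
               orientation = map$orientation,
               stats = as.list(map$stats))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read externally supplied multichannel EGM traces
#'
#' Ingests delimited text (one column per channel, optional header) for
#' entropy analysis of externally recorded electrograms.
#'
#' @param path delimited text file (comma, tab or whitespace).
#' @param fs sampling rate in Hz.
#' @param header logical; does the file carry column names?
#' @return list of `egm_trace` objects, one per channel.
#' @export
read_egm_table <- function(path, fs, header = FALSE) {
  stopifnot(fs > 0)
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else ""
  df <- utils::read.table(path, header = header, sep = sep)
  if (!all(vapply(df, is.numeric, logical(1))))
    stop("non-numeric columns in EGM table")
  lapply(seq_along(df), function(k) {
    structure(list(samples = df[[k]],
                   t = (seq_len(nrow(df)) - 1) / fs * 1000,
                   fs = fs, kind = "external",
                   config = list(position = c(x = NA, y = NA),
                                 spacing_s = NA, orientation = NA,
                                 height_h = NA, source_mode = NA,
                                 channel = names(df)[k])),
              class = "egm_trace")
  })
}
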