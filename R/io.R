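#' Read a probe-level table
#'
#' Reads the plain delimited probe-table format (header required; tab or
#' comma delimited, auto-detected): columns `probeset_id`, `k`, `L`, `pm`,
#' `mm` and optionally `is_control`, `control_region`. A table without an
#' `mm` column is loaded in PM-only mode with a warning.
#'
#' @param path file path.
#' @param ... passed to [chip_data()] (e.g. `reverse_k`).
#' @return a `chip_data` object.
#' @export
read_probe_table <- function(path, ...) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  required <- c("probeset_id", "k", "pm")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("probe table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  for (cn in intersect(c("k", "L", "pm", "mm"), names(df))) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & !is.na(df[[cn]]) & df[[cn]] != "NA")
    if (length(bad))
      stop("non-numeric '", cn, "' at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), " of ", path)
    df[[cn]] <- v
  }
  if (is.null(df$mm))
    warning("no 'mm' column in ", path, "; PM-only mode engaged")
  chip_data(df, metadata = list(source = path), ...)
}

#' Write a probe-level table
#'
#' @param chip a `chip_data` object.
#' @param path output file; delimiter chosen by extension (`.csv` comma,
#'   otherwise tab).
#' @return `path`, invisibly.
#' @export
write_probe_table <- function(chip, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::write.table(chip$probes, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write the analysis summary and curve tables
#'
#' Serializes the scalar summary record as JSON (deterministic field order)
#' and the smoothed hook, degradation-hook and tongs curves plus decay
#' profiles as tab-delimited tables next to it (`<stem>_<curve>.tsv`).
#'
#' @param x a `deg_summary`.
#' @param path path of the JSON summary file.
#' @return named vector of all files written, invisibly.
#' @export
write_summary <- function(x, path) {
  stopifnot(inherits(x, "deg_summary"))
  rec <- summary_record(x)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  stem <- sub("\\.json$", "", path)
  files <- c(summary = path)
  wr <- function(df, name) {
    f <- paste0(stem, "_", name, ".tsv")
    utils::write.table(as.data.frame(df), f, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    files[[name]] <<- f
  }
  if (!is.null(x$hook_curve)) wr(x$hook_curve, "hook")
  wr(x$deghook, "deghook")
  wr(x$tongs, "tongs")
  if (!is.null(x$profile_s_k)) wr(x$profile_s_k, "decay_s_k")
  if (!is.null(x$profile_n_k)) wr(x$profile_n_k, "decay_n_k")
  if (!is.null(x$profile_s_L)) wr(x$profile_s_L, "decay_s_L")
  if (!is.null(x$controls)) wr(x$controls, "controls")
  invisible(files)
}

#' Read back a JSON summary record
#' @param path JSON file written by [write_summary()].
#' @return named list of scalars.
#' @export
read_summary <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
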