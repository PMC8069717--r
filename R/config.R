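#' Read a pipeline configuration from a plain-text file
#'
#' The format is `key = value`, one per line, `#` comments allowed.
#' Hierarchical keys use dots: `synthetic.*` feeds
#' [synth_cohort_config()], `relieff.*` feeds [relief_config()], all other
#' keys are [pipeline_config()] arguments. Values are parsed as numbers,
#' `TRUE`/`FALSE`, or comma-separated lists; anything else stays a string.
#'
#' @param path Config file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  kv <- lapply(lines, function(l) {
    at <- regexpr("=", l, fixed = TRUE)
    key <- trimws(substr(l, 1L, at - 1L))
    val <- trimws(substr(l, at + 1L, nchar(l)))
    list(key = key, value = parse_config_value(val))
  })
  args <- list(); syn <- list(); rel <- list()
  for (e in kv) {
    if (startsWith(e$key, "synthetic.")) {
      syn[[sub("^synthetic\\.", "", e$key)]] <- e$value
    } else if (startsWith(e$key, "relieff.")) {
      rel[[sub("^relieff\\.", "", e$key)]] <- e$value
    } else {
      args[[e$key]] <- e$value
    }
  }
  if (length(syn)) args$synthetic <- do.call(synth_cohort_config, syn)
  if (length(rel)) args$relieff <- do.call(relief_config, rel)
  do.call(pipeline_config, args)
}

parse_config_value <- function(v) {
  if (grepl(",", v, fixed = TRUE)) {
    parts <- trimws(strsplit(v, ",", fixed = TRUE)[[1L]])
    return(unname(sapply(parts, parse_config_value)))
  }
  if (toupper(v) %in% c("TRUE", "FALSE")) return(as.logical(toupper(v)))
  n <- suppressWarnings(as.numeric(v))
  if (!is.na(n)) return(n)
  v
}

#' Write an evaluation report as CSV + JSON
#'
#' The per-subject metric table goes to `<path>.csv` and the full report
#' (per-split detail, selected channels, log) to `<path>.json`.
#'
#' @param report An `evaluation_report` from [run_pipeline()].
#' @param path Output stem (no extension).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  utils::write.csv(report$per_subject, paste0(path, ".csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(per_subject = report$per_subject, per_rep = report$per_rep,
         single_features = report$single_features,
         selected_channels = report$selected_channels, log = report$log),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
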