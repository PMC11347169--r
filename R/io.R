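#' Read and write trace tables
#'
#' Traces are stored as plain tabular text (comma-separated) with columns
#' `trace_id`, `time_s` and one or both of `position_nm`, `position_bp`.
#' Numeric columns round-trip at full precision. Each trace must sit on a
#' strictly increasing uniform time grid; gaps must be marked with explicit
#' `NA` position rows rather than missing rows. Malformed input is rejected
#' with the offending row number, never silently repaired.
#'
#' @param path File path.
#' @param geometry Optional [substrate_geometry()]; when the file declares
#'   only `position_nm`, the bp-domain series is attached via
#'   [displacement_to_nt()].
#' @return `read_traces()`: tibble of traces. `write_traces()`: `path`,
#'   invisibly.
#' @export
read_traces <- function(path, geometry = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           trace_id = readr::col_character(),
                           .default = readr::col_double()))
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(paste0("malformed rows in ", path, ": row(s) ",
                 paste(unique(probs$row), collapse = ", ")))
  }
  if (!"trace_id" %in% names(raw)) raw$trace_id <- "trace_1"
  has_nm <- "position_nm" %in% names(raw)
  has_bp <- "position_bp" %in% names(raw)
  if (!"time_s" %in% names(raw) || (!has_nm && !has_bp)) {
    abort("trace table needs time_s and position_nm and/or position_bp")
  }
  offset <- 0L
  for (tr in split(raw, factor(raw$trace_id, unique(raw$trace_id)))) {
    dt <- diff(tr$time_s)
    bad <- which(dt <= 0 | abs(dt - dt[1]) > 1e-9)
    if (length(bad) > 0) {
      abort(sprintf(
        "non-uniform or non-increasing time grid in trace '%s' at row %d",
        tr$trace_id[1], offset + bad[1] + 1L))
    }
    offset <- offset + nrow(tr)
  }
  if (!has_bp && !is.null(geometry)) {
    raw$position_bp <- displacement_to_nt(raw$position_nm, geometry)
  }
  as_tibble(raw)
}

#' @rdname read_traces
#' @param traces Tibble of traces (`trace_id`, `time_s`, position columns).
#' @export
write_traces <- function(traces, path) {
  stopifnot(is.data.frame(traces))
  readr::write_csv(traces, path)
  invisible(path)
}

#' Write a segments table
#'
#' @param segments Segment tibble from [segment_ensemble()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  stopifnot(is.data.frame(segments))
  readr::write_csv(segments, path)
  invisible(path)
}

#' Write a condition summary as a flat key-value report
#'
#' @param summary A `condition_summary` (or a list of them).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  if (inherits(summary, "condition_summary")) summary <- list(summary)
  long <- map_dfr(summary, function(s) {
    tidyr::pivot_longer(s$table, -"condition", names_to = "key",
                        values_to = "value",
                        values_transform = as.character)
  })
  readr::write_tsv(long, path)
  invisible(path)
}
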