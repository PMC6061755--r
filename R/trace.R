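#' Construct a detector trace
#'
#' A trace is a tibble with strictly increasing `time` (minutes) and finite
#' `intensity` (detector units), carrying the detector id as an attribute.
#'
#' @param df Data frame with columns `time` (or `time_min`) and `intensity`.
#' @param detector One of `"CAD"`, `"UV"`, `"EIC"`, `"TIC"`.
#' @return A tibble of class `trace`.
#' @export
as_trace <- function(df, detector = c("CAD", "UV", "EIC", "TIC")) {
  detector <- match.arg(detector)
  if ("time_min" %in% names(df) && !"time" %in% names(df)) {
    df$time <- df$time_min
  }
  stopifnot(all(c("time", "intensity") %in% names(df)))
  out <- tibble::tibble(time = as.numeric(df$time),
                        intensity = as.numeric(df$intensity))
  if (nrow(out) < 2) stop("a trace needs at least 2 points", call. = FALSE)
  if (is.unsorted(out$time, strictly = TRUE)) {
    stop("trace times must be strictly increasing", call. = FALSE)
  }
  if (!all(is.finite(out$intensity))) {
    stop("trace intensities must be finite", call. = FALSE)
  }
  if ("baseline" %in% names(df)) out$baseline <- as.numeric(df$baseline)
  attr(out, "detector") <- detector
  class(out) <- c("trace", class(out))
  out
}

#' Read a trace from a two-column CSV
#'
#' Expects a header with columns `time_min` (or `time`) and `intensity`.
#' The detector id is inferred from the file name (e.g. `"*_cad.csv"`)
#' unless given explicitly.
#'
#' @param path CSV path.
#' @param detector Detector id; default guessed from the file name, falling
#'   back to `"CAD"`.
#' @return A [as_trace()] tibble.
#' @export
read_trace <- function(path, detector = NULL) {
  if (is.null(detector)) {
    nm <- tolower(basename(path))
    detector <- c("CAD", "UV", "EIC", "TIC")[
      match(TRUE, vapply(c("cad", "uv", "eic", "tic"), grepl, logical(1),
                         x = nm), nomatch = 1L)]
  }
  as_trace(utils::read.csv(path), detector)
}

#' Write a trace to CSV
#'
#' @param trace A trace tibble.
#' @param path Output CSV path (columns `time_min`, `intensity`).
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(
    data.frame(time_min = trace$time, intensity = trace$intensity),
    path, row.names = FALSE)
  invisible(path)
}

trace_detector <- function(trace) attr(trace, "detector") %||% "CAD"
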