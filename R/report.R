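#' Pipeline configuration
#'
#' All tunable thresholds of the analysis pipeline in one nested list, with
#' the defaults the package documents. [read_config()] merges a YAML file
#' over these defaults.
#'
#' @return Nested named list.
#' @export
botanicad_config <- function() {
  list(
    chromatogram = list(
      min_snr = 3,
      min_rel_area = 0.05,     # percent of total CAD signal (TTC floor)
      baseline_lambda = 1e9,
      baseline_p = 0.001,
      smooth_window = 9L,
      include_hump = FALSE     # hook: add the hump integral to the total
    ),
    ms = list(
      tol_ppm = 10,
      min_intensity = 0,
      min_scans = 3L,
      max_charge = 2L,
      rt_window = 0.05
    ),
    formula = list(
      tol_ppm = 5,
      adducts_pos = c("[M+H]+", "[M+NH4]+", "[M+Na]+"),
      adducts_neg = c("[M-H]-", "[M+HCOO]-"),
      nitrogen_rule = TRUE,
      weights = scoring_weights()
    ),
    fusion = list(
      margin = 0.1,
      offset = 0,
      low_level_fraction = 0.1,
      standard_rt_tol = 0.1
    ),
    report = list(
      count_formula_only_as_identified = FALSE
    ),
    run = list(
      ion_source = "ESI"       # metadata only; APCI runs record it here
    )
  )
}

#' Read a pipeline configuration from YAML
#'
#' Values in the file override the [botanicad_config()] defaults
#' recursively; unknown keys are kept (forward-compatible hooks).
#'
#' @param path YAML path; `NULL` returns the defaults.
#' @return Nested named list.
#' @export
read_config <- function(path = NULL) {
  cfg <- botanicad_config()
  if (is.null(path)) return(cfg)
  utils::modifyList(cfg, yaml::read_yaml(path))
}

#' Assemble the constituent report
#'
#' Joins the per-peak quantitation with the per-peak analyte assignments
#' into the package's report object: one record per CAD peak (coeluting
#' analytes listed within the record), MS-only analyte groups appended as
#' below-floor entries flagged `"< floor%"`, and summary statistics for a
#' TTC-style safety assessment.
#'
#' @param assignments Per-peak assignment table from [peak_assignments()],
#'   where each peak's groups carry `name`, `cas`, `formula`, `adducts`,
#'   `ppm_error`, `score` and `tier` columns (see [annotate_groups()]).
#' @param quant Peak table with `cad_percent` ([relative_quantitation()]).
#' @param below_floor Optional tibble of unassigned (MS-only) groups.
#' @param floor Reporting floor in percent (for the below-floor flag text).
#' @param count_formula_only_as_identified Interpretation switch for the
#'   unknown summary: when `FALSE` (default) a record with a formula but no
#'   proposed name still counts as unidentified.
#' @return An object of class `extract_report`: list with `records`,
#'   `below_floor` and `summary`.
#' @export
build_report <- function(assignments, quant, below_floor = NULL,
                         floor = 0.05,
                         count_formula_only_as_identified = FALSE) {
  if (nrow(quant) == 0 && nrow(assignments) == 0) {
    report <- list(
      records = tibble::tibble(peak = integer(0), proposed_id = character(0),
                               cas = character(0), formula = character(0),
                               tier = character(0), cad_percent = numeric(0),
                               n_analytes = integer(0), coelution = logical(0),
                               low_level_extra = logical(0),
                               comment = character(0), analytes = list()),
      below_floor = tibble::tibble(),
      summary = list(n_peaks = 0L, max_unknown_percent = 0,
                     total_unidentified_percent = 0, floor = floor))
    class(report) <- "extract_report"
    return(report)
  }
  orphan_q <- setdiff(quant$peak, assignments$peak)
  orphan_a <- setdiff(assignments$peak, quant$peak)
  if (length(orphan_q) || length(orphan_a)) {
    stop("peak numbers do not match between quantitation and assignments; ",
         "orphans: ", paste(c(orphan_q, orphan_a), collapse = ", "),
         call. = FALSE)
  }
  tier_rank <- c(standard_match = 1, proposed = 2, formula_only = 3,
                 unknown_no_ms = 4)
  records <- quant |>
    dplyr::select("peak", "cad_percent") |>
    dplyr::left_join(assignments, by = "peak") |>
    dplyr::arrange(.data$peak)
  pull_field <- function(g, field, collapse = "; ") {
    if (is.null(g) || nrow(g) == 0 || !field %in% names(g)) return(NA_character_)
    v <- g[[field]]
    v <- v[!is.na(v) & nzchar(as.character(v))]
    if (length(v) == 0) return(NA_character_)
    paste(unique(as.character(v)), collapse = collapse)
  }
  records$proposed_id <- vapply(records$groups, function(g) {
    out <- pull_field(g, "name")
    if (is.na(out)) "Unknown" else out
  }, character(1))
  records$cas <- vapply(records$groups, pull_field, character(1), "cas")
  records$formula <- vapply(records$groups, pull_field, character(1), "formula")
  records$tier <- vapply(records$groups, function(g) {
    if (is.null(g) || nrow(g) == 0 || !"tier" %in% names(g)) {
      return("unknown_no_ms")
    }
    g$tier[which.min(tier_rank[g$tier])]
  }, character(1))
  records$comment <- vapply(records$groups, pull_field, character(1), "comment")
  records <- records |>
    dplyr::rename(analytes = "groups") |>
    dplyr::relocate("peak", "proposed_id", "cas", "formula", "tier",
                    "cad_percent", "n_analytes", "coelution",
                    "low_level_extra", "comment")
  bf <- below_floor
  if (!is.null(bf) && nrow(bf) > 0) {
    bf$flag <- paste0("< ", format(floor), "%")
  } else {
    bf <- tibble::tibble()
  }
  report <- list(records = records, below_floor = bf,
                 summary = c(list(n_peaks = nrow(records)),
                             .unknown_stats(records,
                                            count_formula_only_as_identified),
                             list(floor = floor)))
  class(report) <- "extract_report"
  report
}

.unknown_stats <- function(records, count_formula_only_as_identified) {
  unidentified <- records$tier == "unknown_no_ms" |
    (records$tier == "formula_only" &
       (records$proposed_id == "Unknown" | is.na(records$proposed_id)))
  if (count_formula_only_as_identified) {
    unidentified <- records$tier == "unknown_no_ms"
  }
  pct <- records$cad_percent[unidentified]
  list(
    max_unknown_percent = if (length(pct)) max(pct) else 0,
    total_unidentified_percent = if (length(pct)) sum(pct) else 0
  )
}

#' Unknown-constituent summary of a report
#'
#' The two numbers a TTC assessment needs about the unidentified signal:
#' the largest single unidentified constituent (percent of total CAD
#' signal) and the total unidentified percentage. A record counts as
#' unidentified when it has no proposed name and no standard match; by
#' default a bare molecular formula does not make a record identified
#' (configurable).
#'
#' @param report An `extract_report`.
#' @param count_formula_only_as_identified Flip the interpretation so that
#'   any record with an MS formula counts as identified.
#' @return Named list `max_unknown_percent`, `total_unidentified_percent`.
#' @export
unknown_summary <- function(report,
                            count_formula_only_as_identified = FALSE) {
  stopifnot(inherits(report, "extract_report"))
  .unknown_stats(report$records, count_formula_only_as_identified)
}

#' @export
print.extract_report <- function(x, ...) {
  cat("Extract constituent report:", x$summary$n_peaks, "CAD peaks")
  if (nrow(x$below_floor)) {
    cat(";", nrow(x$below_floor), "MS-only analytes below the",
        paste0(format(x$summary$floor), "%"), "floor")
  }
  cat("\n  largest unidentified constituent:",
      sprintf("%.2f%%", x$summary$max_unknown_percent),
      "\n  total unidentified signal:",
      sprintf("%.2f%%", x$summary$total_unidentified_percent), "\n\n")
  print(dplyr::select(x$records, -"analytes"), ...)
  invisible(x)
}

#' @rdname tidy.extract_report
#' @export
tidy.extract_report <- function(x, ...) {
  dplyr::select(x$records, -"analytes")
}

#' Tidy and glance methods for extract reports
#'
#' `tidy()` returns the per-peak records as a flat tibble; `glance()`
#' returns a one-row summary (peak count, unknown statistics).
#'
#' @param x An `extract_report`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy.extract_report
#' @export
glance.extract_report <- function(x, ...) {
  tibble::as_tibble(x$summary[c("n_peaks", "max_unknown_percent",
                                "total_unidentified_percent", "floor")])
}
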