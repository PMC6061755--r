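#' Packaged constituent table of the reference ginkgo characterization
#'
#' A machine-readable transcription of the published characterization of a
#' standardized *Ginkgo biloba* leaf extract: 83 CAD peaks and the analytes
#' proposed for each (113 records; coeluting analytes share a peak number).
#' Comments are compressed to a confidence tier plus evidence keywords.
#' The per-peak CAD percentage column is `NA`: the source's supplementary
#' percentages are not distributed with the package (see
#' [table1_synthetic_percentages()] for a synthetic stand-in).
#'
#' @return Tibble with columns `peak`, `name`, `cas`, `formula`, `adducts`
#'   (";"-separated extra observed adducts), `tier`, `low_level_extra`,
#'   `comment`, `cad_percent` (all `NA`).
#' @examples
#' dplyr::n_distinct(table1_fixture()$peak) # 83
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_constituents.csv",
                      package = "botanicad", mustWork = TRUE)
  df <- tibble::as_tibble(
    utils::read.csv(path, colClasses = c(
      peak = "integer", name = "character", cas = "character",
      formula = "character", adducts = "character", tier = "character",
      low_level_extra = "logical", comment = "character")))
  df$cad_percent <- NA_real_
  df
}

#' Deterministic retention-time grid for the packaged constituent table
#'
#' Assigns evenly spaced retention times (4 to 122 minutes, emulating a
#' 125-minute gradient separation) to the 83 CAD peak numbers, for building
#' synthetic chromatograms from the packaged fixture.
#'
#' @return Tibble with columns `peak` and `rt` (minutes).
#' @export
table1_retention_grid <- function() {
  peaks <- sort(unique(table1_fixture()$peak))
  tibble::tibble(peak = peaks,
                 rt = 4 + (seq_along(peaks) - 1) * 118 / (length(peaks) - 1))
}

#' Synthetic per-peak CAD percentages for the packaged constituent table
#'
#' The source's per-peak percentages are not distributed with the package,
#' so this generates a SYNTHETIC, deterministic allocation that respects
#' the published summary constraints: every peak at or above the 0.05%
#' reporting floor, unidentified peaks totalling 10% of the CAD signal
#' with no single one above 1.2%, and the remaining 90% shared among
#' identified peaks (peaks confirmed by authentic standards weighted
#' double). It is a stand-in for exercising report assembly and summary
#' statistics, not a reproduction of the measured values.
#'
#' @return Tibble with columns `peak` and `cad_percent` (sums to 100).
#' @export
table1_synthetic_percentages <- function() {
  tab <- table1_fixture()
  per_peak <- tab |>
    dplyr::group_by(.data$peak) |>
    dplyr::summarise(
      identified = any(.data$name != "Unknown" & nzchar(.data$name)),
      has_standard = any(.data$tier == "standard_match"),
      .groups = "drop")
  un <- which(!per_peak$identified)
  n_un <- length(un)
  # geometric series from the 1.2% ceiling down, scaled to total 10%
  q <- stats::uniroot(function(q) 1.2 * (1 - q^n_un) / (1 - q) - 10,
                      c(0.5, 0.99), tol = 1e-12)$root
  pct <- numeric(nrow(per_peak))
  pct[un] <- 1.2 * q^(seq_len(n_un) - 1)
  pct[un] <- pct[un] * 10 / sum(pct[un])
  w <- ifelse(per_peak$has_standard, 2, 1)[-un]
  pct[-un] <- 90 * w / sum(w)
  tibble::tibble(peak = per_peak$peak, cad_percent = pct)
}

#' Assemble the packaged constituent table into a report object
#'
#' Builds an `extract_report` from the packaged transcription, using the
#' synthetic percentage allocation ([table1_synthetic_percentages()]) for
#' the `cad_percent` column, so report-level summaries (unknown ceiling,
#' unidentified total) can be computed on the published constituent
#' structure.
#'
#' @return An `extract_report`.
#' @export
table1_report <- function() {
  tab <- table1_fixture()
  tier_rank <- c(standard_match = 1, proposed = 2, formula_only = 3,
                 unknown_no_ms = 4)
  records <- tab |>
    dplyr::group_by(.data$peak) |>
    dplyr::summarise(
      proposed_id = {
        nm <- .data$name[.data$name != "Unknown" & nzchar(.data$name)]
        if (length(nm)) paste(unique(nm), collapse = "; ") else "Unknown"
      },
      cas = paste(stats::na.omit(unique(.data$cas[nzchar(.data$cas)])),
                  collapse = "; "),
      formula = paste(unique(.data$formula[!is.na(.data$formula) &
                                             nzchar(.data$formula)]),
                      collapse = "; "),
      tier = .data$tier[which.min(tier_rank[.data$tier])],
      n_analytes = dplyr::n(),
      coelution = dplyr::n() >= 2,
      low_level_extra = any(.data$low_level_extra),
      comment = paste(unique(.data$comment[nzchar(.data$comment)]),
                      collapse = "; "),
      analytes = list(dplyr::pick(dplyr::everything())),
      .groups = "drop") |>
    dplyr::left_join(table1_synthetic_percentages(), by = "peak") |>
    dplyr::arrange(.data$peak)
  report <- list(records = records, below_floor = tibble::tibble(),
                 summary = c(list(n_peaks = nrow(records)),
                             .unknown_stats(records, FALSE),
                             list(floor = 0.05)))
  class(report) <- "extract_report"
  report
}

# Constituent table for simulating the 83-peak chromatogram: one
# constituent per CAD peak (first listed analyte), synthetic percentages as
# mass fractions, deterministic retention grid. Peaks without a molecular
# formula (the Mg cluster and the no-MS peaks) get a surrogate formula --
# only their CAD behaviour is of interest.
table1_constituents <- function() {
  tab <- table1_fixture() |>
    dplyr::group_by(.data$peak) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  out <- tab |>
    dplyr::select("peak", "name", "formula") |>
    dplyr::left_join(table1_retention_grid(), by = "peak") |>
    dplyr::left_join(table1_synthetic_percentages(), by = "peak") |>
    dplyr::transmute(
      name = .data$name,
      formula = dplyr::if_else(
        is.na(.data$formula) | !nzchar(.data$formula) | .data$formula == "Mg",
        "C20H30O10", .data$formula),
      rt = .data$rt,
      fraction = .data$cad_percent)
  out$fraction <- out$fraction * 100 / sum(out$fraction)
  constituent_table(out)
}
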