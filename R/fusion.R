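#' Calibrate a constant inter-detector time offset
#'
#' In a serial UHPLC/UV/CAD/MS stack the detectors see each analyte at
#' slightly different times (post-column split transit). Given apex times
#' of the same analytes matched across two detectors, the offset is the
#' median of the pairwise differences, robust to occasional mismatches.
#'
#' @param matched Data frame with columns `time_a` and `time_b` (minutes),
#'   one row per matched analyte (>= 1 row).
#' @return The scalar offset `t_b - t_a` (minutes); apply as
#'   `t_a + offset = t_b`. `calibrate_offset` of the swapped columns gives
#'   the negated value (antisymmetry).
#' @export
calibrate_offset <- function(matched) {
  stopifnot(is.data.frame(matched),
            all(c("time_a", "time_b") %in% names(matched)))
  if (nrow(matched) == 0) stop("no matched apex pairs", call. = FALSE)
  stats::median(matched$time_b - matched$time_a)
}

#' Assign analyte groups to CAD peaks
#'
#' A group is assigned to the CAD peak whose `[rt_left - margin,
#' rt_right + margin]` window contains the group's offset-corrected apex;
#' when windows overlap, the peak with the nearest apex wins
#' (deterministic). Groups matching no peak are flagged `below_floor`: the
#' analyte was seen by MS but not by CAD, hence is present below the CAD
#' reporting floor.
#'
#' @param peaks CAD peak table ([detect_peaks()]).
#' @param groups Analyte-group table ([group_adducts()]).
#' @param offset Constant detector offset `t_CAD - t_MS` (minutes), from
#'   [calibrate_offset()]; 0 when uncalibrated.
#' @param margin Window slack (minutes, default 0.1).
#' @return `groups` with columns `peak` (CAD peak number, `NA` when
#'   unassigned) and `below_floor` appended.
#' @export
assign_groups_to_peaks <- function(peaks, groups, offset = 0, margin = 0.1) {
  if (nrow(groups) == 0) {
    groups$peak <- integer(0)
    groups$below_floor <- logical(0)
    return(groups)
  }
  rt_cad <- groups$rt + offset
  idx <- vapply(rt_cad, function(rt) {
    hit <- which(peaks$rt_left - margin <= rt & rt <= peaks$rt_right + margin)
    if (length(hit) == 0) return(NA_integer_)
    if (length(hit) > 1) hit <- hit[which.min(abs(peaks$rt_apex[hit] - rt))]
    hit
  }, integer(1))
  groups$peak <- peaks$peak[idx]
  groups$below_floor <- is.na(groups$peak)
  groups
}

#' Summarise analyte assignments per CAD peak
#'
#' Counts the distinct analyte groups inside each CAD peak. Groups whose
#' EIC area falls below `low_level_fraction` of the peak's top group are
#' not counted as coeluting analytes; they set the `low_level_extra`
#' flag instead (low-level extra MS signals, presumed below the level of
#' interest).
#'
#' @param peaks CAD peak table.
#' @param assigned Output of [assign_groups_to_peaks()].
#' @param low_level_fraction Area fraction below which an extra group only
#'   raises the flag (default 0.1).
#' @return One row per CAD peak: `peak`, `n_analytes`, `coelution`,
#'   `low_level_extra`, and `groups` (list column of that peak's groups,
#'   ranked by EIC area).
#' @export
peak_assignments <- function(peaks, assigned, low_level_fraction = 0.1) {
  per_peak <- assigned |>
    dplyr::filter(!is.na(.data$peak)) |>
    dplyr::group_by(.data$peak) |>
    dplyr::arrange(dplyr::desc(.data$area), .by_group = TRUE) |>
    dplyr::summarise(
      n_analytes = sum(.data$area >= low_level_fraction * max(.data$area)),
      low_level_extra = dplyr::n() > sum(.data$area >=
                                           low_level_fraction * max(.data$area)),
      groups = list(dplyr::pick(dplyr::everything())),
      .groups = "drop")
  out <- tibble::tibble(peak = peaks$peak) |>
    dplyr::left_join(per_peak, by = "peak") |>
    dplyr::mutate(
      n_analytes = dplyr::coalesce(.data$n_analytes, 0L),
      low_level_extra = dplyr::coalesce(.data$low_level_extra, FALSE),
      coelution = .data$n_analytes >= 2L) |>
    dplyr::relocate("peak", "n_analytes", "coelution", "low_level_extra")
  out
}

#' Identification confidence tier
#'
#' Vectorized tier assignment from the evidence available for each
#' (peak, analyte) record:
#' \describe{
#'   \item{standard_match}{retention time and formula agree with an
#'     authentic reference standard.}
#'   \item{proposed}{MS signal present, top formula candidate at or above
#'     the confident score, and external annotation text (literature or
#'     MS/MS interpretation) supplied.}
#'   \item{formula_only}{MS signal present; a formula, but no supported
#'     structure proposal.}
#'   \item{unknown_no_ms}{no discernible MS signal for the CAD peak.}
#' }
#'
#' @param standard_match Logical: matched an authentic standard.
#' @param ms_present Logical: any MS signal for the record.
#' @param score Top candidate score (0-100; `NA` when no MS).
#' @param annotation Optional annotation text (`NA` = none).
#' @param confident_score Score threshold for a confident formula
#'   (default 90).
#' @return Character vector of tiers.
#' @export
assign_confidence_tier <- function(standard_match, ms_present, score,
                                   annotation = NA_character_,
                                   confident_score = 90) {
  n <- max(lengths(list(standard_match, ms_present, score, annotation)))
  standard_match <- rep_len(standard_match, n)
  ms_present <- rep_len(ms_present, n)
  score <- rep_len(score, n)
  annotation <- rep_len(annotation, n)
  dplyr::case_when(
    standard_match ~ "standard_match",
    ms_present & !is.na(score) & score >= confident_score &
      !is.na(annotation) & nzchar(annotation) ~ "proposed",
    ms_present ~ "formula_only",
    .default = "unknown_no_ms"
  )
}

#' Match analyte groups to reference standards
#'
#' A group matches a standard when its neutral mass agrees with the
#' standard's formula within `tol_ppm` and its apex time with the
#' standard's expected retention time within `rt_tol`.
#'
#' @param groups Analyte-group table.
#' @param standards Data frame with columns `name`, `formula`, `rt`
#'   (minutes; expected in the MS time frame) and optional `cas`.
#' @param rt_tol Retention-time tolerance (minutes, default 0.1).
#' @param tol_ppm Mass tolerance (default 10).
#' @return `groups` with `standard_name` and `standard_cas` columns
#'   (`NA` when unmatched).
#' @export
match_reference_standards <- function(groups, standards, rt_tol = 0.1,
                                      tol_ppm = 10) {
  if (is.null(standards) || nrow(standards) == 0) {
    groups$standard_name <- NA_character_
    groups$standard_cas <- NA_character_
    return(groups)
  }
  standards$mass <- monoisotopic_mass(standards$formula)
  hit <- vapply(seq_len(nrow(groups)), function(i) {
    ok <- which(abs(standards$mass - groups$neutral_mass[i]) <=
                  standards$mass * tol_ppm * 1e-6 &
                  abs(standards$rt - groups$rt[i]) <= rt_tol)
    if (length(ok) == 0) return(NA_integer_)
    ok[which.min(abs(standards$rt[ok] - groups$rt[i]))]
  }, integer(1))
  groups$standard_name <- standards$name[hit]
  groups$standard_cas <- if ("cas" %in% names(standards)) {
    standards$cas[hit]
  } else {
    NA_character_
  }
  groups
}

#' Read a reference-standard table
#'
#' CSV with header `name, formula, rt` and optional `cas`.
#'
#' @param path CSV path.
#' @return Tibble of standards.
#' @export
read_standards <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path))
  stopifnot(all(c("name", "formula", "rt") %in% names(df)))
  df
}
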