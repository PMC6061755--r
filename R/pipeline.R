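#' Annotate analyte groups with formula assignments and confidence tiers
#'
#' For each analyte group, enumerates candidate molecular formulas for its
#' most intense member ion, scores them against the member's observed
#' isotope envelope, and keeps the top-ranked candidate. Identification
#' evidence is then folded into a confidence tier: an authentic-standard
#' match (from [match_reference_standards()]) dominates; otherwise a
#' confident formula plus external annotation text gives a proposed
#' identification; otherwise the record stays formula-only.
#'
#' @param groups Analyte-group table ([group_adducts()]), optionally
#'   carrying `standard_name`/`standard_cas` columns.
#' @param config Pipeline configuration ([botanicad_config()]).
#' @param annotations Optional tibble mapping `formula` to a proposed
#'   `name`, optional `cas` and `annotation` text (stand-in for literature
#'   and MS/MS interpretation, which the package does not automate).
#' @param elements Isotope table.
#' @return `groups` with `name`, `cas`, `formula`, `ppm_error`, `score`,
#'   `confident` and `tier` columns appended.
#' @export
annotate_groups <- function(groups, config = botanicad_config(),
                            annotations = NULL,
                            elements = element_table()) {
  n <- nrow(groups)
  cols <- list(formula = NA_character_, ppm_error = NA_real_,
               score = NA_real_, confident = NA)
  for (nm in names(cols)) groups[[nm]] <- rep(cols[[nm]], n)
  if (!"standard_name" %in% names(groups)) {
    groups$standard_name <- rep(NA_character_, n)
    groups$standard_cas <- rep(NA_character_, n)
  }
  wts <- config$formula$weights
  for (i in seq_len(n)) {
    m <- groups$members[[i]]
    rep_row <- m[which.max(m$area), ]
    env <- rep_row$envelope[[1]]
    obs <- observed_envelope(env$mz, env$intensity,
                             charge = rep_row$charge,
                             polarity = rep_row$polarity)
    cand <- enumerate_candidates(
      rep_row$mz, rep_row$polarity, adducts = rep_row$adduct,
      tol_ppm = config$formula$tol_ppm,
      nitrogen_rule = config$formula$nitrogen_rule,
      elements = elements)
    if (nrow(cand) == 0) next
    top <- rank_candidates(
      score_candidates(cand, obs, weights = wts, elements = elements))[1, ]
    groups$formula[i] <- top$formula
    groups$ppm_error[i] <- top$ppm_error
    groups$score[i] <- top$score
    groups$confident[i] <- top$confident
  }
  ann_name <- rep(NA_character_, n)
  ann_cas <- rep(NA_character_, n)
  ann_text <- rep(NA_character_, n)
  if (!is.null(annotations) && nrow(annotations) > 0) {
    j <- match(groups$formula, annotations$formula)
    ann_name <- annotations$name[j]
    if ("cas" %in% names(annotations)) ann_cas <- annotations$cas[j]
    if ("annotation" %in% names(annotations)) {
      ann_text <- annotations$annotation[j]
    } else {
      ann_text <- ifelse(is.na(ann_name), NA_character_, "annotated")
    }
  }
  groups$tier <- assign_confidence_tier(
    standard_match = !is.na(groups$standard_name),
    ms_present = TRUE,
    score = groups$score,
    annotation = ann_text,
    confident_score = wts$confident)
  groups$name <- dplyr::coalesce(groups$standard_name, ann_name)
  groups$cas <- dplyr::coalesce(groups$standard_cas, ann_cas)
  groups$comment <- dplyr::case_when(
    groups$tier == "standard_match" ~ "authentic standard",
    groups$tier == "proposed" ~ "proposed from annotation",
    .default = NA_character_)
  groups
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full extract-characterization pipeline
#'
#' Executes baseline estimation, CAD peak detection and quantitation, MS
#' feature detection and adduct grouping, formula assignment, detector
#' fusion and report assembly, optionally writing all artifacts (peak
#' table, feature table, report CSV + JSON, and a log of every threshold
#' used) to a directory. Partial artifacts are removed if a stage fails.
#'
#' @param cad A CAD trace tibble or path to a trace CSV.
#' @param spectra A centroid spectra tibble or path (mzML / JSON).
#' @param config Pipeline configuration ([botanicad_config()] /
#'   [read_config()]).
#' @param standards Optional reference-standard table (or CSV path); used
#'   both for tier-1 confirmation and for calibrating the CAD-MS time
#'   offset from matched apexes.
#' @param annotations Optional annotation table, see [annotate_groups()].
#' @param out_dir Optional output directory for artifacts.
#' @return An `extract_report` (invisibly carries attributes `peaks`,
#'   `features`, `groups` with the intermediate tables).
#' @export
run_pipeline <- function(cad, spectra, config = botanicad_config(),
                         standards = NULL, annotations = NULL,
                         out_dir = NULL) {
  if (is.character(cad)) cad <- .stage("read_cad", read_trace(cad, "CAD"))
  if (is.character(spectra)) spectra <- .stage("read_ms", read_spectra(spectra))
  if (is.character(standards)) standards <- read_standards(standards)
  cc <- config$chromatogram
  cad <- .stage("baseline", estimate_baseline(
    cad, lambda = cc$baseline_lambda, p = cc$baseline_p))
  peaks <- .stage("detect_peaks", detect_peaks(
    cad, min_snr = cc$min_snr, min_rel_area = cc$min_rel_area,
    smooth_window = cc$smooth_window))
  if (nrow(peaks) == 0) {
    stop("pipeline stage 'detect_peaks' failed: no peaks detected at ",
         "min_snr = ", cc$min_snr, ", floor = ", cc$min_rel_area, "%",
         call. = FALSE)
  }
  quant <- .stage("quantitation", relative_quantitation(peaks))
  quant <- .stage("shape_metrics", tryCatch(
    usp_shape_metrics(cad, quant), error = function(e) quant))
  mc <- config$ms
  features <- .stage("detect_features", detect_features(
    spectra, min_intensity = mc$min_intensity, tol_ppm = mc$tol_ppm,
    max_charge = mc$max_charge, min_scans = mc$min_scans))
  groups <- .stage("group_adducts", group_adducts(
    features, tol_ppm = mc$tol_ppm, rt_window = mc$rt_window))
  offset <- config$fusion$offset
  if (!is.null(standards) && nrow(groups) > 0) {
    groups <- .stage("standards", match_reference_standards(
      groups, standards, rt_tol = config$fusion$standard_rt_tol,
      tol_ppm = mc$tol_ppm))
  }
  groups <- .stage("formula_assignment", annotate_groups(
    groups, config = config, annotations = annotations))
  assigned <- .stage("fusion", assign_groups_to_peaks(
    peaks, groups, offset = offset, margin = config$fusion$margin))
  assignments <- .stage("fusion", peak_assignments(
    peaks, assigned, low_level_fraction = config$fusion$low_level_fraction))
  report <- .stage("report", build_report(
    assignments, quant,
    below_floor = dplyr::filter(assigned, .data$below_floor),
    floor = cc$min_rel_area,
    count_formula_only_as_identified =
      config$report$count_formula_only_as_identified))
  attr(report, "peaks") <- quant
  attr(report, "features") <- features
  attr(report, "groups") <- groups
  if (!is.null(out_dir)) {
    .stage("artifacts", write_report_artifacts(report, config, out_dir))
  }
  report
}

#' Write report artifacts to a directory
#'
#' Writes `peaks.csv` (detected peak table with shape metrics and CAD
#' percentages), `features.csv`, `report.csv` (flat records),
#' `report.json` (versioned schema: records, below-floor entries, summary)
#' and `config.json` (every threshold used). On error, files already
#' written are removed.
#'
#' @param report An `extract_report` from [run_pipeline()].
#' @param config The configuration used.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report_artifacts <- function(report, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  on_fail <- function(e) {
    unlink(written)
    stop(e)
  }
  tryCatch({
    emit <- function(name, writer) {
      path <- file.path(out_dir, name)
      writer(path)
      written <<- c(written, path)
    }
    peaks <- attr(report, "peaks")
    if (!is.null(peaks)) {
      emit("peaks.csv", function(p) utils::write.csv(peaks, p, row.names = FALSE))
    }
    features <- attr(report, "features")
    if (!is.null(features) && nrow(features) > 0) {
      emit("features.csv", function(p) utils::write.csv(
        dplyr::select(features, -"envelope"), p, row.names = FALSE))
    }
    emit("report.csv", function(p) utils::write.csv(
      tidy(report), p, row.names = FALSE))
    emit("report.json", function(p) jsonlite::write_json(list(
      schema = "botanicad-report/1",
      records = tidy(report),
      below_floor = if (nrow(report$below_floor)) {
        dplyr::select(report$below_floor,
                      dplyr::any_of(c("group", "neutral_mass", "rt",
                                      "formula", "score", "flag")))
      } else {
        list()
      },
      summary = report$summary
    ), p, auto_unbox = TRUE, digits = NA, na = "null"))
    emit("config.json", function(p) jsonlite::write_json(
      config, p, auto_unbox = TRUE, digits = NA, na = "null",
      force = TRUE))
  }, error = on_fail)
  invisible(written)
}
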