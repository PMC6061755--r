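#' Read centroided spectra
#'
#' Reads centroided MS data into the package's long spectra layout: one row
#' per centroid with columns `scan`, `rt` (minutes), `polarity` (`"+"` or
#' `"-"`), `mz` and `intensity`. Supports mzML (via the mzR package) and the
#' package's own plain-JSON spectra format (an array of objects with fields
#' `rt`, `polarity`, `mz`, `intensity`).
#'
#' Profile-mode data are rejected: a centroided pipeline cannot operate on
#' dense profile spectra.
#'
#' @param path Path to an `.mzML` or `.json` file.
#' @return Centroid tibble.
#' @export
read_spectra <- function(path) {
  ext <- tolower(tools::file_ext(path))
  out <- if (ext == "json") {
    scans <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
    purrr::imap_dfr(scans, function(s, i) {
      tibble::tibble(scan = i, rt = as.numeric(s$rt),
                     polarity = s$polarity %||% "+",
                     mz = as.numeric(s$mz),
                     intensity = as.numeric(s$intensity))
    })
  } else if (ext == "mzml") {
    if (!requireNamespace("mzR", quietly = TRUE)) {
      stop("reading mzML requires the mzR package", call. = FALSE)
    }
    h <- mzR::openMSfile(path)
    on.exit(mzR::close(h))
    hd <- mzR::header(h)
    pk <- mzR::peaks(h)
    if (is.matrix(pk)) pk <- list(pk)
    purrr::map_dfr(seq_len(nrow(hd)), function(i) {
      m <- pk[[i]]
      if (nrow(m) == 0) return(NULL)
      tibble::tibble(
        scan = i,
        rt = hd$retentionTime[i] / 60,
        polarity = if (is.null(hd$polarity) || is.na(hd$polarity[i]) ||
                         hd$polarity[i] != 0) "+" else "-",
        mz = m[, 1], intensity = m[, 2])
    })
  } else {
    stop("unsupported spectra format: .", ext, call. = FALSE)
  }
  out <- dplyr::filter(out, .data$intensity > 0)
  check_centroided(out)
  dplyr::arrange(out, .data$polarity, .data$scan, .data$mz)
}

#' Write spectra to the package's JSON format
#'
#' @param spectra Centroid tibble (see [read_spectra()]).
#' @param path Output `.json` path.
#' @export
write_spectra <- function(spectra, path) {
  scans <- spectra |>
    dplyr::group_by(.data$polarity, .data$scan) |>
    dplyr::group_map(function(g, key) {
      list(rt = g$rt[1], polarity = key$polarity, mz = g$mz,
           intensity = g$intensity)
    })
  jsonlite::write_json(scans, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write spectra to mzML
#'
#' Writes one polarity of a centroid tibble to an mzML file via the mzR
#' package (positive and negative acquisitions are separate runs, as on
#' the instrument).
#'
#' @param spectra Centroid tibble.
#' @param path Output `.mzML` path.
#' @param polarity Which polarity to write (default the first present).
#' @export
write_mzml <- function(spectra, path, polarity = NULL) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("writing mzML requires the mzR package", call. = FALSE)
  }
  polarity <- polarity %||% spectra$polarity[1]
  sp <- dplyr::filter(spectra, .data$polarity == !!polarity)
  scans <- split(sp, sp$scan)
  n <- length(scans)
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = if (polarity == "+") 1L else 0L,
    peaksCount = vapply(scans, nrow, integer(1)),
    totIonCurrent = vapply(scans, function(s) sum(s$intensity), numeric(1)),
    retentionTime = vapply(scans, function(s) s$rt[1] * 60, numeric(1)),
    basePeakMZ = vapply(scans, function(s) s$mz[which.max(s$intensity)],
                        numeric(1)),
    basePeakIntensity = vapply(scans, function(s) max(s$intensity),
                               numeric(1)),
    collisionEnergy = 0, ionisationEnergy = 0, lowMZ = 50, highMZ = 3200,
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_,
    isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_)
  pks <- lapply(scans, function(s) cbind(mz = s$mz, intensity = s$intensity))
  mzR::writeMSData(object = pks, file = path, header = hdr)
  invisible(path)
}

# Heuristic profile-mode detection: centroid data have sparse, well-
# separated peaks per scan; profile data sample a dense m/z raster.
check_centroided <- function(spectra, max_dense_fraction = 0.2) {
  gaps <- spectra |>
    dplyr::group_by(.data$polarity, .data$scan) |>
    dplyr::summarise(
      n = dplyr::n(),
      dense = if (dplyr::n() > 1) mean(diff(.data$mz) < 0.01) else 0,
      .groups = "drop")
  if (nrow(gaps) > 0 &&
      stats::weighted.mean(gaps$dense, gaps$n) > max_dense_fraction) {
    stop("spectra look like profile mode (dense m/z raster); ",
         "centroid the data first", call. = FALSE)
  }
  invisible(spectra)
}
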