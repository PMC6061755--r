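#' Extracted ion chromatogram
#'
#' Per-scan summed intensity of all centroids within `+/- tol_ppm` of the
#' target m/z; scans with no matching centroid contribute zero, so the EIC
#' covers the full acquisition.
#'
#' @param spectra Centroid tibble (see [read_spectra()]).
#' @param mz Target m/z.
#' @param tol_ppm Window half-width in ppm (> 0). The default is wider than
#'   formula-assignment tolerances to preserve chromatographic fidelity.
#' @param polarity Restrict to one polarity (default: the first present).
#' @return An EIC trace tibble (`time`, `intensity`).
#' @export
extract_eic <- function(spectra, mz, tol_ppm = 10, polarity = NULL) {
  if (tol_ppm <= 0) stop("tol_ppm must be positive", call. = FALSE)
  polarity <- polarity %||% spectra$polarity[1]
  sp <- dplyr::filter(spectra, .data$polarity == !!polarity)
  grid <- dplyr::distinct(sp, .data$scan, .data$rt)
  tol <- mz * tol_ppm * 1e-6
  hits <- sp |>
    dplyr::filter(abs(.data$mz - !!mz) <= tol) |>
    dplyr::group_by(.data$scan) |>
    dplyr::summarise(intensity = sum(.data$intensity), .groups = "drop")
  out <- grid |>
    dplyr::left_join(hits, by = "scan") |>
    dplyr::mutate(intensity = dplyr::coalesce(.data$intensity, 0)) |>
    dplyr::arrange(.data$rt)
  as_trace(tibble::tibble(time = out$rt, intensity = out$intensity), "EIC")
}

# Cluster sorted centroids into m/z channels: break at gaps wider than the
# ppm tolerance, then split each channel into contiguous scan runs.
.ion_traces <- function(sp, tol_ppm, min_scans, min_intensity) {
  sp <- dplyr::arrange(sp, .data$mz)
  gap <- c(TRUE, diff(sp$mz) > sp$mz[-nrow(sp)] * 2 * tol_ppm * 1e-6)
  sp$channel <- cumsum(gap)
  # one point per channel and scan (coeluting same-channel centroids sum)
  sp <- sp |>
    dplyr::group_by(.data$channel, .data$scan) |>
    dplyr::summarise(
      mz = stats::weighted.mean(.data$mz, .data$intensity),
      rt = .data$rt[1],
      intensity = sum(.data$intensity),
      .groups = "drop")
  scans <- sort(unique(sp$scan))
  traces <- sp |>
    dplyr::mutate(scan_index = match(.data$scan, scans)) |>
    dplyr::group_by(.data$channel) |>
    dplyr::arrange(.data$scan_index, .by_group = TRUE) |>
    dplyr::mutate(run = cumsum(c(1L, diff(.data$scan_index) > 1L))) |>
    dplyr::group_by(.data$channel, .data$run) |>
    dplyr::summarise(
      mz = stats::weighted.mean(.data$mz, .data$intensity),
      n_scans = dplyr::n(),
      apex_scan = .data$scan[which.max(.data$intensity)],
      apex_rt = .data$rt[which.max(.data$intensity)],
      apex_intensity = max(.data$intensity),
      area = if (dplyr::n() > 1) pracma::trapz(.data$rt, .data$intensity)
             else .data$intensity[1] * 0,
      .groups = "drop")
  dplyr::filter(traces, .data$n_scans >= min_scans,
                .data$apex_intensity >= min_intensity)
}

#' Detect deisotoped MS features
#'
#' Tracks centroids across adjacent scans into ion traces (>= `min_scans`
#' consecutive scans), then merges co-apexing traces spaced by `1.00336/z`
#' Da (z = 1..`max_charge`) into one feature per isotope envelope. The
#' monoisotopic member is the lowest-mass envelope member; an isolated
#' trace becomes a singleton feature with charge defaulted to 1.
#'
#' @param spectra Centroid tibble.
#' @param min_intensity Minimum apex intensity of an ion trace.
#' @param tol_ppm m/z matching tolerance (scan-to-scan and isotope spacing).
#' @param max_charge Highest charge state considered (default 2).
#' @param min_scans Minimum consecutive scans per ion trace (default 3).
#' @return Tibble of features: `feature`, `polarity`, `mz` (monoisotopic),
#'   `charge`, `rt` (apex, min), `area` (EIC area of the monoisotopic
#'   trace), `envelope` (list column: tibble `mz`, `intensity` ordered A,
#'   A+1, ...).
#' @export
detect_features <- function(spectra, min_intensity = 0, tol_ppm = 10,
                            max_charge = 2L, min_scans = 3L) {
  check_centroided(spectra)
  out <- purrr::map_dfr(split(spectra, spectra$polarity), function(sp) {
    pol <- sp$polarity[1]
    tr <- .ion_traces(sp, tol_ppm, min_scans, min_intensity)
    if (nrow(tr) == 0) return(NULL)
    tr <- dplyr::arrange(tr, .data$mz)
    used <- logical(nrow(tr))
    feats <- list()
    iso_spacing <- 1.00336
    for (i in seq_len(nrow(tr))) {
      if (used[i]) next
      used[i] <- TRUE
      best <- list(members = i, z = 1L)
      for (z in seq_len(max_charge)) {
        members <- i
        k <- 1L
        repeat {
          target <- tr$mz[i] + k * iso_spacing / z
          tol <- target * 2 * tol_ppm * 1e-6
          cand <- which(!used & abs(tr$mz - target) <= tol &
                          abs(tr$apex_scan - tr$apex_scan[i]) <= 2L)
          if (length(cand) == 0) break
          cand <- cand[which.max(tr$apex_intensity[cand])]
          members <- c(members, cand)
          k <- k + 1L
        }
        if (length(members) > length(best$members)) {
          best <- list(members = members, z = z)
        }
      }
      used[best$members] <- TRUE
      env <- tr[best$members, ]
      feats[[length(feats) + 1L]] <- tibble::tibble(
        polarity = pol,
        mz = env$mz[1],
        charge = best$z,
        rt = env$apex_rt[1],
        area = env$area[1],
        envelope = list(tibble::tibble(mz = env$mz,
                                       intensity = env$apex_intensity)))
    }
    dplyr::bind_rows(feats)
  })
  if (nrow(out) == 0) return(out)
  out <- dplyr::arrange(out, .data$rt, .data$mz)
  out$feature <- seq_len(nrow(out))
  dplyr::relocate(out, "feature")
}

#' Group adduct-related features into analyte groups
#'
#' Features whose implied neutral masses (inverting the adduct arithmetic
#' for every adduct compatible with their polarity and charge) agree within
#' `tol_ppm`, and whose apex times agree within `rt_window`, are merged
#' into one analyte group with a single consensus neutral mass. Grouping is
#' greedy from the most intense feature; the adduct hypothesis explaining
#' the most features wins, with ties broken by the smallest neutral-mass
#' disagreement. Each feature receives exactly one adduct assignment;
#' unexplained features become singleton groups under the polarity's
#' default adduct (`[M+H]+` / `[M-H]-`, or their doubly charged analogues).
#'
#' @param features Feature tibble from [detect_features()].
#' @param adducts Adduct table or character vector of names (default: the
#'   full [adduct_table()]).
#' @param tol_ppm Neutral-mass agreement tolerance.
#' @param rt_window Apex agreement window (minutes).
#' @return Tibble of groups: `group`, `neutral_mass`, `rt`, `n_members`,
#'   `area` (summed member EIC area), `members` (list column of features
#'   with their `adduct` assignment).
#' @export
group_adducts <- function(features, adducts = NULL, tol_ppm = 10,
                          rt_window = 0.05) {
  if (nrow(features) == 0) {
    return(tibble::tibble(group = integer(0), neutral_mass = numeric(0),
                          rt = numeric(0), n_members = integer(0),
                          area = numeric(0), members = list()))
  }
  adducts <- if (is.null(adducts)) adduct_table() else .as_adduct_tbl(adducts)
  # candidate neutral masses per feature x compatible adduct
  cand <- purrr::map_dfr(seq_len(nrow(features)), function(i) {
    f <- features[i, ]
    ad <- adducts[adducts$polarity == f$polarity &
                    abs(adducts$charge) == f$charge, , drop = FALSE]
    if (nrow(ad) == 0) return(NULL)
    tibble::tibble(
      feature_row = i,
      adduct = ad$adduct,
      neutral = vapply(seq_len(nrow(ad)), function(j) {
        neutral_mass(f$mz, ad[j, ])
      }, numeric(1)))
  })
  ord <- order(-features$area, features$mz)
  assigned <- rep(NA_integer_, nrow(features))
  adduct_of <- rep(NA_character_, nrow(features))
  group_id <- 0L
  for (i in ord) {
    if (!is.na(assigned[i])) next
    my <- cand[cand$feature_row == i, , drop = FALSE]
    best <- NULL
    for (j in seq_len(nrow(my))) {
      m0 <- my$neutral[j]
      tol <- m0 * tol_ppm * 1e-6
      mate <- cand[is.na(assigned[cand$feature_row]) &
                     cand$feature_row != i &
                     abs(cand$neutral - m0) <= tol, , drop = FALSE]
      mate <- mate[abs(features$rt[mate$feature_row] - features$rt[i]) <=
                     rt_window, , drop = FALSE]
      if (nrow(mate) > 0) {
        mate <- mate |>
          dplyr::mutate(dev = abs(.data$neutral - m0)) |>
          dplyr::group_by(.data$feature_row) |>
          dplyr::slice_min(.data$dev, n = 1, with_ties = FALSE) |>
          dplyr::ungroup()
      }
      score <- nrow(mate)
      dev_tot <- if (nrow(mate) > 0) sum(abs(mate$neutral - m0)) else 0
      if (is.null(best) || score > best$score ||
          (score == best$score && dev_tot < best$dev_tot)) {
        best <- list(j = j, score = score, dev_tot = dev_tot, mate = mate)
      }
    }
    group_id <- group_id + 1L
    if (is.null(best) || best$score == 0) {
      # no adduct-consistent partner: singleton under the default adduct
      assigned[i] <- group_id
      adduct_of[i] <- .default_adduct(features$polarity[i], features$charge[i])
    } else {
      assigned[i] <- group_id
      adduct_of[i] <- my$adduct[best$j]
      for (k in seq_len(nrow(best$mate))) {
        fr <- best$mate$feature_row[k]
        assigned[fr] <- group_id
        adduct_of[fr] <- best$mate$adduct[k]
      }
    }
  }
  features$group <- assigned
  features$adduct <- adduct_of
  features$implied_neutral <- vapply(seq_len(nrow(features)), function(i) {
    neutral_mass(features$mz[i], adduct_table(features$adduct[i]))
  }, numeric(1))
  out <- features |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      neutral_mass = stats::weighted.mean(.data$implied_neutral,
                                          .data$area + 1e-300),
      rt = stats::weighted.mean(.data$rt, .data$area + 1e-300),
      n_members = dplyr::n(),
      area = sum(.data$area),
      members = list(dplyr::pick(dplyr::everything())),
      .groups = "drop") |>
    dplyr::arrange(.data$rt, .data$neutral_mass)
  out$group <- seq_len(nrow(out))
  out
}

.default_adduct <- function(polarity, charge = 1L) {
  if (polarity == "+") {
    if (charge >= 2) "[M+2H]2+" else "[M+H]+"
  } else {
    if (charge >= 2) "[M-2H]2-" else "[M-H]-"
  }
}
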