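# Scaled complementary error function exp(z^2) * erfc(z); asymptotic series
# for large z where the direct product overflows.
.erfcx <- function(z) {
  out <- numeric(length(z))
  small <- z <= 25
  out[small] <- pracma::erfcx(z[small])
  if (any(!small)) {
    zz <- z[!small]
    out[!small] <- (1 - 0.5 / zz^2 + 0.75 / zz^4) / (zz * sqrt(pi))
  }
  out
}

#' Exponentially modified Gaussian peak profile
#'
#' Analytic EMG with unit parameters: a Gaussian of width `sigma` convolved
#' with an exponential decay of time constant `tau`, scaled to total area
#' `area`. Evaluated in a numerically stable form (scaled complementary
#' error function near the apex, direct form in the far tail);
#' `tau = 0` degenerates to a pure Gaussian. Chromatographic tailing in the
#' simulator uses this shape so USP metrics take non-trivial values.
#'
#' @param t Time points (minutes).
#' @param mu Retention time of the underlying Gaussian (minutes).
#' @param sigma Gaussian width (minutes, > 0).
#' @param tau Exponential tailing constant (minutes, >= 0); negative values
#'   produce a mirror-image fronting peak.
#' @param area Total peak area (units * min).
#' @return Intensity values at `t`.
#' @export
emg_peak <- function(t, mu, sigma, tau = 0, area = 1) {
  stopifnot(sigma > 0)
  if (tau < 0) return(emg_peak(2 * mu - t, mu, sigma, -tau, area))
  if (tau < 1e-9) {
    return(area / (sigma * sqrt(2 * pi)) * exp(-(t - mu)^2 / (2 * sigma^2)))
  }
  z <- (sigma / tau - (t - mu) / sigma) / sqrt(2)
  out <- numeric(length(t))
  pos <- z >= 0
  out[pos] <- area / (2 * tau) * exp(-(t[pos] - mu)^2 / (2 * sigma^2)) *
    .erfcx(z[pos])
  if (any(!pos)) {
    ex <- sigma^2 / (2 * tau^2) - (t[!pos] - mu) / tau
    out[!pos] <- area / (2 * tau) * exp(ex) * pracma::erfc(z[!pos])
  }
  out
}

#' Simulation configuration
#'
#' Acquisition and noise settings for [simulate_extract()], emulating the
#' instrument stack the package targets: CAD sampled at 10 Hz, centroid
#' Q-TOF spectra at 5 Hz, a broad baseline hump under the peaks, additive
#' detector noise and ppm-scale mass jitter. A seed is mandatory: identical
#' seed and configuration give identical outputs.
#'
#' @param seed Integer RNG seed (mandatory).
#' @param cad_rate_hz CAD sampling rate (Hz).
#' @param scan_rate_hz MS scan rate (Hz).
#' @param noise_sd Absolute CAD noise standard deviation (detector units);
#'   when `NULL` it is calibrated so the smallest constituent peak has apex
#'   signal-to-noise `noise_floor_snr`.
#' @param noise_floor_snr Default-noise calibration: the apex S/N that a
#'   hypothetical peak at the 0.05% reporting floor (median width) would
#'   have (default 10, a clean acquisition).
#' @param hump_amplitude Baseline hump apex height as a fraction of the
#'   tallest peak (0 disables); emulates a chromatographically unresolved
#'   tannin hump.
#' @param hump_sigma,hump_center Hump width and center (minutes; center
#'   `NULL` = middle of the run).
#' @param mass_error_ppm Per-centroid m/z jitter (1 sigma, ppm).
#' @param abundance_error_pct Per-centroid multiplicative intensity jitter
#'   (1 sigma, percent).
#' @param offset_ms Detector time offset t_CAD - t_MS (minutes).
#' @param cad_total_area Total CAD area shared among constituents
#'   (units * min).
#' @param ms_scale Intensity scale of the most responsive MS feature.
#' @param prune Isotope-envelope pruning threshold for generated spectra.
#' @return Named list of settings.
#' @export
simulation_config <- function(seed, cad_rate_hz = 10, scan_rate_hz = 5,
                              noise_sd = NULL, noise_floor_snr = 10,
                              hump_amplitude = 0.2, hump_sigma = 15,
                              hump_center = NULL, mass_error_ppm = 0,
                              abundance_error_pct = 0, offset_ms = 0,
                              cad_total_area = 1e4, ms_scale = 1e6,
                              prune = 1e-3) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  stopifnot(cad_rate_hz > 0, scan_rate_hz > 0, noise_floor_snr >= 0,
            hump_amplitude >= 0, mass_error_ppm >= 0,
            abundance_error_pct >= 0)
  as.list(environment())
}

#' Ground-truth constituent table
#'
#' Validating constructor for the simulator input: one row per constituent
#' with name, molecular formula, retention time, relative mass fraction
#' (percent; must sum to 100), per-polarity adduct lists (`";"`-separated
#' adduct names), an ionization response factor, and EMG shape parameters.
#'
#' @param df Data frame with columns `name`, `formula`, `rt`, `fraction`;
#'   optional `adducts_pos` (default `"[M+H]+"`), `adducts_neg` (default
#'   `"[M-H]-"`), `response` (default 1), `sigma` (min, default 0.05),
#'   `tau` (min, default 0.02).
#' @return Validated tibble.
#' @export
constituent_table <- function(df) {
  stopifnot(all(c("name", "formula", "rt", "fraction") %in% names(df)))
  out <- tibble::as_tibble(df)
  defaults <- list(adducts_pos = "[M+H]+", adducts_neg = "[M-H]-",
                   response = 1, sigma = 0.05, tau = 0.02)
  for (nm in names(defaults)) {
    if (!nm %in% names(out)) out[[nm]] <- defaults[[nm]]
  }
  if (abs(sum(out$fraction) - 100) > 1e-6) {
    stop("constituent fractions must sum to 100", call. = FALSE)
  }
  stopifnot(all(out$sigma > 0))
  invisible(lapply(out$formula, parse_formula))
  out
}

#' Simulate a synthetic botanical extract
#'
#' Renders a ground-truth constituent list into the raw data the analysis
#' pipeline consumes: a CAD trace (sum of tailed-Gaussian peaks with area
#' proportional to mass fraction, on a broad baseline hump, plus Gaussian
#' noise), a UV trace, and centroided MS spectra in which each constituent
#' contributes its adduct isotope envelopes scaled by the response factor,
#' with optional per-centroid ppm and abundance jitter. Identical seed and
#' configuration give identical output.
#'
#' @param constituents A [constituent_table()].
#' @param sim A [simulation_config()].
#' @return List with elements `cad` (trace), `uv` (trace), `spectra`
#'   (centroid tibble, both polarities), and `truth` (constituents with the
#'   generated per-peak areas, heights and neutral masses, plus the noise
#'   sd actually used).
#' @export
simulate_extract <- function(constituents, sim) {
  constituents <- constituent_table(constituents)
  set.seed(sim$seed)
  cs <- constituents
  if (any(diff(sort(cs$rt)) < 0.1 * stats::median(cs$sigma))) {
    warning("constituent retention times overlap very closely", call. = FALSE)
  }
  t_end <- max(cs$rt) + max(cs$sigma) * 8 + 1
  t_cad <- seq(0, t_end, by = 1 / (60 * sim$cad_rate_hz))
  cs$area <- sim$cad_total_area * cs$fraction / 100
  signal <- rep(0, length(t_cad))
  height <- numeric(nrow(cs))
  for (i in seq_len(nrow(cs))) {
    pk <- emg_peak(t_cad, cs$rt[i], cs$sigma[i], cs$tau[i], cs$area[i])
    height[i] <- max(pk)
    signal <- signal + pk
  }
  cs$height <- height
  hump <- 0
  if (sim$hump_amplitude > 0) {
    ctr <- sim$hump_center %||% (t_end / 2)
    hump <- sim$hump_amplitude * max(height) *
      exp(-(t_cad - ctr)^2 / (2 * sim$hump_sigma^2))
  }
  # default noise anchored to the reporting floor: a hypothetical peak of
  # 0.05% of the total area (median width) has apex S/N = noise_floor_snr
  h_floor <- sim$cad_total_area * 5e-4 /
    (stats::median(cs$sigma) * sqrt(2 * pi))
  noise_sd <- sim$noise_sd %||%
    (if (sim$noise_floor_snr > 0) h_floor / sim$noise_floor_snr else 0)
  cad_y <- signal + hump +
    (if (noise_sd > 0) stats::rnorm(length(t_cad), 0, noise_sd) else 0)
  cad <- as_trace(tibble::tibble(time = t_cad, intensity = cad_y), "CAD")
  uv <- as_trace(tibble::tibble(time = t_cad, intensity = signal), "UV")

  spectra <- .simulate_spectra(cs, sim, t_end)
  cs$neutral_mass <- monoisotopic_mass(cs$formula)
  cs$noise_sd <- noise_sd
  list(cad = cad, uv = uv, spectra = spectra, truth = cs)
}

.simulate_spectra <- function(cs, sim, t_end) {
  scan_dt <- 1 / (60 * sim$scan_rate_hz)
  t_scan <- seq(0, t_end, by = scan_dt)
  rows <- list()
  for (pol in c("+", "-")) {
    col <- if (pol == "+") "adducts_pos" else "adducts_neg"
    for (i in seq_len(nrow(cs))) {
      adds <- strsplit(cs[[col]][i], ";")[[1]]
      adds <- adds[nzchar(adds)]
      if (length(adds) == 0) next
      # MS elution profile follows the CAD peak shape, shifted by the
      # detector offset (MS sees the analyte earlier/later than the CAD)
      rt_ms <- cs$rt[i] - sim$offset_ms
      prof <- emg_peak(t_scan, rt_ms, cs$sigma[i], cs$tau[i], 1)
      on <- which(prof > 0.01 * max(prof))
      if (length(on) == 0) next
      for (k in seq_along(adds)) {
        w <- 2^(-(k - 1))            # secondary adducts at half intensity
        pat <- isotope_pattern(cs$formula[i], prune = sim$prune,
                               adduct = adds[k])
        for (s in on) {
          inten <- sim$ms_scale * cs$response[i] * (cs$fraction[i] / 100) *
            w * prof[s] / max(prof) * pat$abundance / 100
          mz <- pat$mz
          if (sim$mass_error_ppm > 0) {
            mz <- mz * (1 + stats::rnorm(length(mz), 0,
                                         sim$mass_error_ppm * 1e-6))
          }
          if (sim$abundance_error_pct > 0) {
            inten <- inten * pmax(0.01, 1 + stats::rnorm(
              length(inten), 0, sim$abundance_error_pct / 100))
          }
          rows[[length(rows) + 1L]] <- tibble::tibble(
            scan = s, rt = t_scan[s], polarity = pol, mz = mz,
            intensity = inten)
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(scan = integer(0), rt = numeric(0),
                          polarity = character(0), mz = numeric(0),
                          intensity = numeric(0)))
  }
  out |>
    dplyr::group_by(.data$scan, .data$polarity) |>
    dplyr::arrange(.data$mz, .by_group = TRUE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$polarity, .data$scan, .data$mz)
}
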