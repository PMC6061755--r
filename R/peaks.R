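.local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

.mad_noise <- function(r) 1.4826 * stats::median(abs(r - stats::median(r)))

# Savitzky-Golay smoothed copy used only to locate apexes and valleys;
# heights and areas are always measured on the raw residual.
.smooth_residual <- function(r, window) {
  window <- min(window, if (length(r) %% 2 == 0) length(r) - 1 else length(r))
  if (window < 5) return(r)
  if (window %% 2 == 0) window <- window - 1L
  signal::sgolayfilt(r, p = 3, n = window)
}

#' Detect chromatographic peaks
#'
#' Finds local maxima of the baseline-subtracted signal, bounds each peak at
#' the flanking valleys (shared valleys split fused peaks at the minimum)
#' with a fallback to the baseline re-crossing, and filters on signal-to-
#' noise and on relative area. Detection operates on a lightly smoothed
#' (Savitzky-Golay) copy of the residual, as chromatographic integrators
#' do: `snr = height / noise`, where height is the maximum of the smoothed
#' baseline-subtracted signal within the bounds and noise is `1.4826 *` the
#' median absolute deviation of the smoothed residual in peak-free regions.
#' Areas are integrated on the unsmoothed residual. The relative-area floor
#' is applied in a second pass, after the total area of all S/N-passing
#' peaks is known, so "percent of total CAD signal" is well defined.
#'
#' @param trace A trace tibble carrying a `baseline` column (see
#'   [estimate_baseline()]).
#' @param min_snr Minimum signal-to-noise ratio (default 3). A degenerate
#'   noiseless input (noise estimate 0) is an error unless `min_snr = 0`.
#' @param min_rel_area Reporting floor as percent of total detected signal
#'   (default 0.05, the TTC-driven floor).
#' @param smooth_window Savitzky-Golay window (samples, odd) used to locate
#'   apexes and valleys.
#' @return Tibble of peaks numbered in elution order: `peak`, `rt_apex`,
#'   `rt_left`, `rt_right`, `height`, `area`, `snr`.
#' @export
detect_peaks <- function(trace, min_snr = 3, min_rel_area = 0.05,
                         smooth_window = 9L) {
  if (!"baseline" %in% names(trace)) {
    stop("trace has no baseline column; run estimate_baseline() first",
         call. = FALSE)
  }
  t <- trace$time
  r <- trace$intensity - trace$baseline
  rs <- .smooth_residual(r, smooth_window)
  noise <- .mad_noise(rs)
  floor0 <- max(min_snr * noise, 1e-6 * max(rs, 0))
  apexes <- .local_maxima(rs)
  apexes <- apexes[rs[apexes] >= floor0]
  # merge apexes separated by insignificant valleys (depth below 3x the
  # smoothed-signal noise): a noisy peak top must yield one peak, while a
  # genuine valley between fused peaks still splits them
  noise_s <- .mad_noise(rs)
  apexes <- .merge_shallow(rs, apexes, 3 * noise_s)
  if (length(apexes) == 0) {
    return(tibble::tibble(peak = integer(0), rt_apex = numeric(0),
                          rt_left = numeric(0), rt_right = numeric(0),
                          height = numeric(0), area = numeric(0),
                          snr = numeric(0)))
  }
  bounds <- .peak_bounds(rs, apexes, tol = max(3 * noise_s, 1e-9 * max(rs, 0)))
  # refine the noise estimate on peak-free points only
  in_peak <- logical(length(r))
  for (i in seq_along(apexes)) in_peak[bounds$left[i]:bounds$right[i]] <- TRUE
  if (any(!in_peak)) {
    noise <- .mad_noise(rs[!in_peak])
  }
  if (noise == 0 && min_snr > 0 && max(r) > 0) {
    stop("noise estimate is zero with nonzero signal; ",
         "use min_snr = 0 for noiseless input", call. = FALSE)
  }
  height <- vapply(seq_along(apexes), function(i) {
    max(rs[bounds$left[i]:bounds$right[i]])
  }, numeric(1))
  snr <- if (noise > 0) height / noise else rep(Inf, length(height))
  area <- vapply(seq_along(apexes), function(i) {
    idx <- bounds$left[i]:bounds$right[i]
    pracma::trapz(t[idx], r[idx])
  }, numeric(1))
  keep <- snr >= min_snr & area > 0
  apexes <- apexes[keep]; height <- height[keep]
  snr <- snr[keep]; area <- area[keep]
  bounds <- lapply(bounds, `[`, keep)
  # second pass: relative-area floor against the total detected signal
  if (length(area) > 0 && min_rel_area > 0) {
    rel <- 100 * area / sum(area)
    keep <- rel >= min_rel_area
    apexes <- apexes[keep]; height <- height[keep]
    snr <- snr[keep]; area <- area[keep]
    bounds <- lapply(bounds, `[`, keep)
  }
  tibble::tibble(
    peak = seq_along(apexes),
    rt_apex = t[apexes],
    rt_left = t[bounds$left],
    rt_right = t[bounds$right],
    height = height, area = area, snr = snr
  )
}

# Iteratively merge adjacent apexes whose separating valley is shallower
# than `min_depth` below the lower of the two apexes; the lower apex is
# absorbed into the higher one.
.merge_shallow <- function(rs, apexes, min_depth) {
  if (min_depth <= 0 || length(apexes) < 2) return(apexes)
  repeat {
    if (length(apexes) < 2) break
    valley <- vapply(seq_len(length(apexes) - 1L), function(i) {
      min(rs[apexes[i]:apexes[i + 1L]])
    }, numeric(1))
    depth <- pmin(rs[apexes[-length(apexes)]], rs[apexes[-1]]) - valley
    i <- which.min(depth)
    if (depth[i] >= min_depth) break
    drop <- if (rs[apexes[i]] < rs[apexes[i + 1L]]) i else i + 1L
    apexes <- apexes[-drop]
  }
  apexes
}

# Valley-to-valley bounds on the smoothed residual: shared boundaries
# between consecutive apexes at the interior minimum; outer bounds by a
# noise-tolerant descent that stops at the baseline re-crossing (rs <= 0)
# or where the signal turns back up by more than `tol` above the running
# minimum (the valley before an unrelated structure).
.peak_bounds <- function(rs, apexes, tol = 0) {
  n <- length(rs)
  k <- length(apexes)
  walk_out <- function(a, limit, step) {
    j <- a
    best <- a
    bestv <- rs[a]
    while (j != limit) {
      nx <- j + step
      v <- rs[nx]
      if (v <= 0) return(j)
      if (v < bestv) {
        bestv <- v
        best <- nx
      } else if (v - bestv > tol) {
        return(best)
      }
      j <- nx
    }
    best
  }
  left <- integer(k); right <- integer(k)
  for (i in seq_len(k)) {
    a <- apexes[i]
    left[i] <- walk_out(a, if (i > 1) apexes[i - 1] else 1L, -1L)
    right[i] <- walk_out(a, if (i < k) apexes[i + 1] else n, 1L)
  }
  list(left = left, right = right)
}

#' USP peak-shape metrics
#'
#' Measures front/back half-widths of each peak at 5% and 10% of the
#' baseline-subtracted apex height (crossing times by linear interpolation
#' between samples) and computes the USP system-suitability factors:
#' asymmetry factor `A_f = b10 / a10` and tailing factor
#' `T = (a5 + b5) / (2 * a5)`.
#'
#' @param trace Trace tibble with `baseline` column.
#' @param peaks Peak table from [detect_peaks()].
#' @return `peaks` with columns `a5`, `b5`, `a10`, `b10`,
#'   `asymmetry_factor`, `tailing_factor` appended.
#' @export
usp_shape_metrics <- function(trace, peaks) {
  t <- trace$time
  r <- trace$intensity - trace$baseline
  cross <- function(idx_from, idx_to, thr) {
    # walk from apex toward the bound; first sample below thr brackets it
    step <- if (idx_to < idx_from) -1L else 1L
    j <- idx_from
    while (j != idx_to && r[j + step] >= thr) j <- j + step
    if (j == idx_to && r[j] >= thr) return(NA_real_)
    j2 <- j + step
    t[j] + (t[j2] - t[j]) * (r[j] - thr) / (r[j] - r[j2])
  }
  met <- purrr::pmap_dfr(
    peaks[, c("rt_apex", "rt_left", "rt_right")],
    function(rt_apex, rt_left, rt_right) {
      il <- which.min(abs(t - rt_left))
      ir <- which.min(abs(t - rt_right))
      seg <- il:ir
      ia <- seg[which.max(r[seg])]
      h <- r[ia]
      out <- list()
      for (frac in c(0.05, 0.10)) {
        thr <- frac * h
        tl <- cross(ia, il, thr)
        if (is.na(tl)) {
          stop("crossing at ", frac * 100, "% height not bracketed on the ",
               "left side of peak at ", signif(rt_apex, 6), " min",
               call. = FALSE)
        }
        tr <- cross(ia, ir, thr)
        if (is.na(tr)) {
          stop("crossing at ", frac * 100, "% height not bracketed on the ",
               "right side of peak at ", signif(rt_apex, 6), " min",
               call. = FALSE)
        }
        tag <- if (frac == 0.05) "5" else "10"
        out[[paste0("a", tag)]] <- t[ia] - tl
        out[[paste0("b", tag)]] <- tr - t[ia]
      }
      tibble::as_tibble(out)
    })
  out <- dplyr::bind_cols(peaks, met)
  out$asymmetry_factor <- out$b10 / out$a10
  out$tailing_factor <- (out$a5 + out$b5) / (2 * out$a5)
  out
}

#' Relative quantitation as percent of total CAD signal
#'
#' `percent_i = 100 * area_i / sum(area)` over the detected peaks. The total
#' is the sum of baseline-subtracted detected peak areas -- a broad baseline
#' hump (e.g. unresolved tannins) is excluded by construction, since the
#' baseline has already been subtracted.
#'
#' @param peaks Peak table with an `area` column (>= 1 row).
#' @return `peaks` with a `cad_percent` column; percentages sum to 100.
#'   Carries attribute `total_signal = "sum of detected peak areas"`.
#' @export
relative_quantitation <- function(peaks) {
  stopifnot(nrow(peaks) >= 1)
  total <- sum(peaks$area)
  if (total <= 0) stop("total peak area is zero", call. = FALSE)
  out <- dplyr::mutate(peaks, cad_percent = 100 * .data$area / total)
  attr(out, "total_signal") <- "sum of detected peak areas"
  out
}
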