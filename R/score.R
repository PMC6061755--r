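#' Isotope-fit scoring parameters
#'
#' The 0-100 composite score is `100 * (w_mass*S_mass + w_abund*S_abund +
#' w_spacing*S_spacing)`, with Gaussian kernels on the three deviation
#' classes a formula-fit inspects: mass accuracy of the monoisotopic (A)
#' peak, the relative abundances of A+1...A+K against the theoretical
#' envelope, and the exact mass spacing between adjacent envelope peaks.
#' The weights and kernel widths here define this package's score; the
#' defaults (0.4/0.4/0.2; sigma 5 ppm, 10 abundance points, 0.002 Da) give
#' scores above 90 for correct, clean assignments and degrade smoothly with
#' interference.
#'
#' @param w_mass,w_abund,w_spacing Nonnegative weights summing to 1.
#' @param sigma_ppm Mass-accuracy kernel width (ppm).
#' @param sigma_abund Abundance kernel width (relative-abundance points,
#'   base peak = 100).
#' @param sigma_spacing Spacing kernel width (Da).
#' @param depth Envelope depth K: number of peaks beyond A compared
#'   (default 2, i.e. A+1 and A+2).
#' @param confident Score at or above which an assignment is labeled
#'   confident (default 90).
#' @return Named list of scoring parameters.
#' @export
scoring_weights <- function(w_mass = 0.4, w_abund = 0.4, w_spacing = 0.2,
                            sigma_ppm = 5, sigma_abund = 10,
                            sigma_spacing = 0.002, depth = 2L,
                            confident = 90) {
  w <- c(w_mass, w_abund, w_spacing)
  stopifnot(all(w >= 0), abs(sum(w) - 1) < 1e-9,
            sigma_ppm > 0, sigma_abund > 0, sigma_spacing > 0, depth >= 0)
  list(w_mass = w_mass, w_abund = w_abund, w_spacing = w_spacing,
       sigma_ppm = sigma_ppm, sigma_abund = sigma_abund,
       sigma_spacing = sigma_spacing, depth = as.integer(depth),
       confident = confident)
}

#' Observed isotope envelope
#'
#' Light validating constructor for the measured A, A+1, ... peak list of
#' one ion.
#'
#' @param mz Measured m/z values, strictly increasing.
#' @param intensity Measured intensities, > 0 (any scale; abundances are
#'   normalized internally to A = 100).
#' @param charge Absolute charge state of the ion (default 1).
#' @param polarity `"+"` or `"-"`.
#' @return Tibble with columns `mz`, `intensity` and attributes `charge`,
#'   `polarity`.
#' @export
observed_envelope <- function(mz, intensity, charge = 1L, polarity = "+") {
  stopifnot(length(mz) == length(intensity), length(mz) >= 1,
            all(intensity > 0), !is.unsorted(mz, strictly = TRUE))
  out <- tibble::tibble(mz = mz, intensity = intensity)
  attr(out, "charge") <- as.integer(abs(charge))
  attr(out, "polarity") <- polarity
  out
}

.gauss_kernel <- function(dev_over_sigma_sq) exp(-0.5 * dev_over_sigma_sq)

# Score one candidate formula+adduct against one observed envelope.
.score_one <- function(formula, adduct, observed, weights, elements) {
  z_obs <- attr(observed, "charge") %||% 1L
  a <- .adduct_row(adduct)
  if (abs(a$charge) != z_obs) {
    stop("charge mismatch: candidate adduct |z| = ", abs(a$charge),
         " but observed envelope has |z| = ", z_obs, call. = FALSE)
  }
  theo <- isotope_pattern(formula, prune = 1e-6, adduct = a,
                          elements = elements)
  theo <- theo[theo$offset <= weights$depth, ]
  k_eff <- max(nrow(theo) - 1L, 1L)

  obs_ab <- 100 * observed$intensity / observed$intensity[1]
  # match observed peaks to theoretical nucleon offsets
  obs_off <- round((observed$mz - observed$mz[1]) * z_obs / 1.00335)

  # mass accuracy on the A peak
  dppm <- (observed$mz[1] - theo$mz[1]) / theo$mz[1] * 1e6
  s_mass <- .gauss_kernel((dppm / weights$sigma_ppm)^2)

  # abundance and spacing over A+1..A+K
  dev_ab <- numeric(0)
  dev_sp <- numeric(0)
  if (nrow(theo) > 1) {
    for (k in theo$offset[-1]) {
      i <- match(k, obs_off)
      th <- theo[theo$offset == k, ]
      prev_th <- theo[match(k, theo$offset) - 1L, ]
      if (is.na(i)) {
        dev_ab <- c(dev_ab, min(th$abundance, 3 * weights$sigma_abund))
        dev_sp <- c(dev_sp, 3 * weights$sigma_spacing)
      } else {
        dev_ab <- c(dev_ab, obs_ab[i] - th$abundance)
        i_prev <- match(prev_th$offset, obs_off)
        if (is.na(i_prev)) {
          dev_sp <- c(dev_sp, 3 * weights$sigma_spacing)
        } else {
          dev_sp <- c(dev_sp, (observed$mz[i] - observed$mz[i_prev]) -
                        (th$mz - prev_th$mz))
        }
      }
    }
    s_abund <- .gauss_kernel(sum((dev_ab / weights$sigma_abund)^2) / k_eff)
    s_spacing <- .gauss_kernel(sum((dev_sp / weights$sigma_spacing)^2) / k_eff)
  } else {
    # envelope with a bare A peak: nothing to compare beyond mass accuracy
    s_abund <- 1
    s_spacing <- 1
  }
  tibble::tibble(
    s_mass = s_mass, s_abund = s_abund, s_spacing = s_spacing,
    score = 100 * (weights$w_mass * s_mass + weights$w_abund * s_abund +
                     weights$w_spacing * s_spacing)
  )
}

#' Score formula candidates against an observed isotope envelope
#'
#' Adds the 0-100 isotope-fit score and its three components to a candidate
#' table from [enumerate_candidates()]. A score at or above
#' `weights$confident` marks the assignment as confident.
#'
#' @param candidates Tibble with at least `formula` and `adduct` columns.
#' @param observed An [observed_envelope()].
#' @param weights Scoring parameters, see [scoring_weights()].
#' @param elements Isotope table.
#' @return `candidates` with columns `s_mass`, `s_abund`, `s_spacing`,
#'   `score` and `confident` appended.
#' @export
score_candidates <- function(candidates, observed,
                             weights = scoring_weights(),
                             elements = element_table()) {
  stopifnot(nrow(observed) >= 1)
  parts <- purrr::map2_dfr(candidates$formula, candidates$adduct,
                           .score_one, observed = observed,
                           weights = weights, elements = elements)
  out <- dplyr::bind_cols(candidates, parts)
  out$confident <- out$score >= weights$confident
  out
}

#' Rank scored candidates
#'
#' Stable sort by score (descending), then |ppm error| (ascending), then
#' total heteroatom count (ascending), then Hill-string order.
#'
#' @param candidates Scored candidate tibble.
#' @return The same tibble, ordered; empty input passes through.
#' @export
rank_candidates <- function(candidates) {
  if (nrow(candidates) == 0) return(candidates)
  het <- vapply(candidates$formula, function(f) {
    counts <- parse_formula(f)
    sum(counts[setdiff(names(counts), c("C", "H"))])
  }, numeric(1), USE.NAMES = FALSE)
  ord <- order(-candidates$score, abs(candidates$ppm_error), het,
               candidates$formula)
  candidates[ord, ]
}
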