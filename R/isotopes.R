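# Distributions are represented as parallel vectors over nucleon offsets
# 0..K: `p` (probability) and `m` (conditional mean total mass). Convolution
# keeps the representation exact at nucleon-aggregated resolution.
.iso_conv <- function(a, b, kmax) {
  ka <- length(a$p) - 1L
  kb <- length(b$p) - 1L
  kk <- min(ka + kb, kmax)
  p <- numeric(kk + 1L)
  pm <- numeric(kk + 1L)
  for (i in 0:ka) {
    if (a$p[i + 1L] == 0) next
    j <- 0:min(kb, kk - i)
    if (length(j) == 0 || j[1] > min(kb, kk - i)) next
    w <- a$p[i + 1L] * b$p[j + 1L]
    idx <- i + j + 1L
    p[idx] <- p[idx] + w
    pm[idx] <- pm[idx] + w * (a$m[i + 1L] + b$m[j + 1L])
  }
  m <- ifelse(p > 0, pm / p, 0)
  list(p = p, m = m)
}

# n-fold self-convolution by binary exponentiation.
.iso_power <- function(d, n, kmax) {
  acc <- NULL
  base <- d
  while (n > 0) {
    if (n %% 2 == 1) {
      acc <- if (is.null(acc)) base else .iso_conv(acc, base, kmax)
    }
    n <- n %/% 2
    if (n > 0) base <- .iso_conv(base, base, kmax)
  }
  acc
}

.iso_single <- function(el, elements, kmax) {
  x <- elements[elements$element == el, ]
  if (nrow(x) == 0) stop("unknown element symbol: ", el, call. = FALSE)
  kk <- min(max(x$offset), kmax)
  p <- numeric(kk + 1L)
  m <- numeric(kk + 1L)
  keep <- x$offset <= kk
  p[x$offset[keep] + 1L] <- x$abundance[keep]
  m[x$offset[keep] + 1L] <- x$mass[keep]
  list(p = p, m = m)
}

#' Theoretical isotope envelope of a formula or adduct ion
#'
#' Exact multinomial convolution over the element isotope distributions,
#' aggregated at nucleon resolution (A, A+1, A+2, ...) with abundance-
#' weighted centroid masses -- the resolution at which a Q-TOF resolves the
#' envelope. Abundances are normalized so the base (most abundant) peak is
#' exactly 100; peaks below `prune` of the base peak are dropped.
#'
#' @param formula Formula string or named count vector.
#' @param prune Relative-abundance pruning threshold (fraction of base peak),
#'   in (0, 1).
#' @param adduct Optional adduct (name or one-row spec). When given, the
#'   envelope is computed for the ion `n*M + delta` and masses are returned
#'   as m/z (electron mass included, divided by |charge|).
#' @param max_offset Highest nucleon offset retained.
#' @param elements Isotope table.
#' @return Tibble with columns `label` ("A", "A+1", ...), `offset`, `mz`
#'   (centroid mass, or m/z when `adduct` is given) and `abundance`
#'   (base peak = 100).
#' @examples
#' isotope_pattern("C27H30O16")
#' @export
isotope_pattern <- function(formula, prune = 1e-4, adduct = NULL,
                            max_offset = 10L, elements = element_table()) {
  counts <- parse_formula(formula)
  if (length(counts) == 0) stop("empty formula", call. = FALSE)
  stopifnot(prune > 0, prune < 1)
  charge <- 0L
  if (!is.null(adduct)) {
    a <- .adduct_row(adduct)
    charge <- a$charge
    if (charge == 0) stop("adduct charge must be nonzero", call. = FALSE)
    d <- parse_formula(a$delta)
    all_el <- union(names(counts), names(d))
    counts <- stats::setNames(
      a$n * ifelse(all_el %in% names(counts), counts[all_el], 0) +
        ifelse(all_el %in% names(d), d[all_el], 0),
      all_el
    )
    counts <- counts[!is.na(counts) & counts != 0]
    if (any(counts < 0)) stop("adduct removes atoms the formula lacks", call. = FALSE)
  }
  acc <- NULL
  for (el in names(counts)) {
    d <- .iso_power(.iso_single(el, elements, max_offset), counts[[el]], max_offset)
    acc <- if (is.null(acc)) d else .iso_conv(acc, d, max_offset)
  }
  keep <- acc$p >= prune * max(acc$p) & acc$p > 0
  offs <- which(keep) - 1L
  mass <- acc$m[keep]
  if (charge != 0) {
    mass <- (mass - charge * atomic_constants[["electron"]]) / abs(charge)
  }
  tibble::tibble(
    label = ifelse(offs == 0, "A", paste0("A+", offs)),
    offset = offs,
    mz = mass,
    abundance = 100 * acc$p[keep] / max(acc$p)
  )
}
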