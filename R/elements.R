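#' Physical constants (Da)
#'
#' CODATA-recommended electron and proton masses in unified atomic mass units,
#' pinned so that all m/z arithmetic in the package is bit-reproducible.
#' The electron mass matters at sub-5-ppm mass accuracy (~0.55 mDa per charge).
#'
#' @format Named numeric vector with entries `electron` and `proton`.
#' @export
atomic_constants <- c(
  electron = 0.000548579909065,
  proton   = 1.007276466621
)

# Pinned isotope table (NIST Atomic Weights and Isotopic Compositions,
# CODATA-consistent masses). One row per stable isotope; `offset` is the
# nucleon offset from the element's lightest listed isotope.
.element_table_default <- function() {
  rows <- list(
    H  = list(mass = c(1.00782503207, 2.01410177785), ab = c(0.999885, 0.000115)),
    C  = list(mass = c(12.0, 13.00335483507), ab = c(0.9893, 0.0107)),
    N  = list(mass = c(14.00307400443, 15.00010889888), ab = c(0.99636, 0.00364)),
    O  = list(mass = c(15.99491461957, 16.99913175650, 17.99915961286),
              ab = c(0.99757, 0.00038, 0.00205)),
    F  = list(mass = 18.99840316273, ab = 1),
    Na = list(mass = 22.9897692820, ab = 1),
    Mg = list(mass = c(23.985041697, 24.985836976, 25.982592968),
              ab = c(0.7899, 0.1000, 0.1101)),
    P  = list(mass = 30.97376199842, ab = 1),
    S  = list(mass = c(31.9720711744, 32.9714589098, 33.967867004, 35.96708071),
              ab = c(0.9499, 0.0075, 0.0425, 0.0001)),
    Cl = list(mass = c(34.968852682, 36.965902602), ab = c(0.7576, 0.2424)),
    K  = list(mass = c(38.9637064864, 39.963998166, 40.9618252579),
              ab = c(0.932581, 0.000117, 0.067302)),
    Ca = list(mass = c(39.962590863, 41.95861783, 42.95876644, 43.95548156,
                       45.9536890, 47.95252276),
              ab = c(0.96941, 0.00647, 0.00135, 0.02086, 0.00004, 0.00187)),
    Br = list(mass = c(78.9183376, 80.9162897), ab = c(0.5069, 0.4931)),
    I  = list(mass = 126.9044719, ab = 1)
  )
  purrr::imap_dfr(rows, function(x, el) {
    tibble::tibble(
      element = el,
      offset = as.integer(round(x$mass - x$mass[1])),
      mass = x$mass,
      abundance = x$ab
    )
  })
}

#' Element isotope table
#'
#' Returns the isotope masses and natural abundances used throughout the
#' package, as a tibble with one row per stable isotope. The default table is
#' pinned inside the package so isotope-envelope and exact-mass computations
#' are reproducible; it can be overridden from a YAML file mapping element
#' symbols to lists of `[mass, abundance]` pairs.
#'
#' @param yaml Optional path to a YAML override. Elements present in the file
#'   replace the packaged entries; others are kept.
#' @return A tibble with columns `element`, `offset` (nucleon offset from the
#'   lightest isotope), `mass` (Da) and `abundance` (fraction; sums to 1 per
#'   element).
#' @examples
#' element_table()
#' @export
element_table <- function(yaml = NULL) {
  tab <- .element_table_default()
  if (!is.null(yaml)) {
    over <- yaml::read_yaml(yaml)
    repl <- purrr::imap_dfr(over, function(iso, el) {
      m <- vapply(iso, function(p) as.numeric(p[[1]]), numeric(1))
      a <- vapply(iso, function(p) as.numeric(p[[2]]), numeric(1))
      ord <- order(m)
      tibble::tibble(element = el, offset = as.integer(round(m[ord] - min(m))),
                     mass = m[ord], abundance = a[ord])
    })
    tab <- dplyr::bind_rows(dplyr::filter(tab, !.data$element %in% repl$element), repl)
  }
  validate_element_table(tab)
  tab
}

validate_element_table <- function(tab) {
  by_el <- split(tab, tab$element)
  for (el in names(by_el)) {
    x <- by_el[[el]]
    if (abs(sum(x$abundance) - 1) > 1e-6) {
      stop("abundances for element '", el, "' do not sum to 1", call. = FALSE)
    }
    if (is.unsorted(x$mass, strictly = TRUE)) {
      stop("isotope masses for element '", el, "' are not strictly increasing",
           call. = FALSE)
    }
  }
  invisible(tab)
}

# Principal-isotope (most abundant) mass per element, as a named vector.
principal_masses <- function(elements = element_table()) {
  pr <- elements |>
    dplyr::group_by(.data$element) |>
    dplyr::slice_max(.data$abundance, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  stats::setNames(pr$mass, pr$element)
}
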