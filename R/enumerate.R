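#' Element count bounds for formula enumeration
#'
#' Defaults reflect the CHNO-dominated chemistry of plant extracts
#' (flavonoid glycosides, terpene lactones, alkyl phenols): C 0-100,
#' H 0-150, N 0-6, O 0-40. Sulfur (0-3) and phosphorus (0-2) can be enabled
#' with `include_s` / `include_p` or by editing the returned tibble.
#'
#' @param include_s,include_p Add S / P rows with their default ranges.
#' @param max_atoms Cap on the total atom count of a candidate.
#' @return Tibble with columns `element`, `min`, `max`, plus a `max_atoms`
#'   attribute.
#' @export
element_bounds <- function(include_s = FALSE, include_p = FALSE,
                           max_atoms = 300L) {
  tab <- tibble::tribble(
    ~element, ~min, ~max,
    "C", 0L, 100L,
    "H", 0L, 150L,
    "N", 0L, 6L,
    "O", 0L, 40L
  )
  if (include_s) tab <- dplyr::add_row(tab, element = "S", min = 0L, max = 3L)
  if (include_p) tab <- dplyr::add_row(tab, element = "P", min = 0L, max = 2L)
  stopifnot(all(tab$min <= tab$max))
  attr(tab, "max_atoms") <- max_atoms
  tab
}

#' Enumerate candidate molecular formulas for an observed ion
#'
#' Exhaustively yields every formula within the element bounds whose
#' theoretical m/z under any of the supplied adducts falls within `tol_ppm`
#' of the observed m/z. Candidates must pass chemical plausibility filters:
#' DBE >= 0, integer DBE (electron parity of an even-electron ion) and the
#' nitrogen rule for singly charged ions (both toggleable via
#' `nitrogen_rule`), and H <= 2C + N + 2.
#'
#' The search iterates a vectorized counting grid over the non-hydrogen
#' elements and solves the hydrogen count from the mass residual (hydrogen
#' spacing of ~1 Da vastly exceeds any ppm-scale tolerance, so at most one
#' H count can match per grid point).
#'
#' @param mz Observed m/z (> 0).
#' @param polarity `"+"` or `"-"`; adducts of the other polarity are ignored.
#' @param adducts Character vector of adduct names or an adduct tibble
#'   (see [adduct_table()]). Must be nonempty after polarity filtering.
#' @param bounds Element bounds, see [element_bounds()].
#' @param tol_ppm Mass tolerance in ppm (> 0).
#' @param nitrogen_rule Apply parity filters (nitrogen rule + integer DBE)
#'   to singly charged even-electron ions.
#' @param elements Isotope table.
#' @return Tibble of unscored candidates: `formula`, `adduct`, `charge`,
#'   `neutral_mass`, `theoretical_mz`, `ppm_error` (signed, observed minus
#'   theoretical), `dbe`, sorted by |ppm_error|.
#' @examples
#' enumerate_candidates(611.16066, "+", "[M+H]+")
#' @export
enumerate_candidates <- function(mz, polarity = c("+", "-"), adducts = NULL,
                                 bounds = element_bounds(), tol_ppm = 5,
                                 nitrogen_rule = TRUE,
                                 elements = element_table()) {
  stopifnot(mz > 0, tol_ppm > 0)
  polarity <- match.arg(polarity)
  if (is.null(adducts)) {
    adducts <- adduct_table()
  } else {
    adducts <- .as_adduct_tbl(adducts)
  }
  adducts <- adducts[adducts$polarity == polarity, , drop = FALSE]
  if (nrow(adducts) == 0) stop("empty adduct list for polarity ", polarity,
                               call. = FALSE)
  grid_els <- setdiff(bounds$element, "H")
  n_comb <- prod(bounds$max[bounds$element %in% grid_els] -
                   bounds$min[bounds$element %in% grid_els] + 1)
  if (n_comb > 1e7) {
    stop("element bounds imply > 1e7 combinations; narrow the bounds",
         call. = FALSE)
  }
  pm <- principal_masses(elements)
  h_bounds <- bounds[bounds$element == "H", ]
  h_min <- if (nrow(h_bounds)) h_bounds$min else 0L
  h_max <- if (nrow(h_bounds)) h_bounds$max else 0L
  max_atoms <- attr(bounds, "max_atoms") %||% 300L

  grid <- do.call(expand.grid, c(
    stats::setNames(
      purrr::map2(bounds$min[bounds$element %in% grid_els],
                  bounds$max[bounds$element %in% grid_els], seq.int),
      grid_els
    ),
    list(KEEP.OUT.ATTRS = FALSE)
  ))
  grid_mass <- as.vector(as.matrix(grid) %*% pm[grid_els])

  out <- purrr::pmap_dfr(adducts, function(adduct, n, delta, charge, polarity) {
    target <- (abs(charge) * mz + charge * atomic_constants[["electron"]] -
                 delta_mass(delta, elements)) / n
    if (target <= 0) return(NULL)
    tol_da <- target * tol_ppm * 1e-6
    resid <- target - grid_mass
    nh <- as.integer(round(resid / pm[["H"]]))
    ok <- nh >= h_min & nh <= h_max &
      abs(resid - nh * pm[["H"]]) <= tol_da
    if (!any(ok)) return(NULL)
    g <- grid[ok, , drop = FALSE]
    nh <- nh[ok]
    nc <- if ("C" %in% grid_els) g$C else 0L
    nn <- if ("N" %in% grid_els) g$N else 0L
    np <- if ("P" %in% grid_els) g$P else 0L
    d <- nc - nh / 2 + (nn + np) / 2 + 1
    keep <- d >= 0 & nh <= 2 * nc + nn + 2 &
      (rowSums(g) + nh) <= max_atoms & (rowSums(g) + nh) > 0
    if (nitrogen_rule && abs(charge) == 1) {
      nominal <- nh * 1L
      for (el in grid_els) nominal <- nominal + g[[el]] * as.integer(round(pm[[el]]))
      keep <- keep & abs(d - round(d)) < 1e-9 &
        ((nominal %% 2 == 0) == (nn %% 2 == 0))
    }
    if (!any(keep)) return(NULL)
    g <- g[keep, , drop = FALSE]
    nh <- nh[keep]
    d <- d[keep]
    neutral <- grid_mass[ok][keep] + nh * pm[["H"]]
    theo <- (n * neutral + delta_mass(delta, elements) -
               charge * atomic_constants[["electron"]]) / abs(charge)
    counts <- g
    counts$H <- nh
    fstr <- vapply(seq_len(nrow(counts)), function(i) {
      v <- as.integer(counts[i, ])
      names(v) <- names(counts)
      format_formula(v[v > 0])
    }, character(1))
    tibble::tibble(
      formula = fstr, adduct = adduct, charge = charge,
      neutral_mass = neutral, theoretical_mz = theo,
      ppm_error = (mz - theo) / theo * 1e6, dbe = d
    )
  })
  if (nrow(out) == 0) {
    return(tibble::tibble(formula = character(0), adduct = character(0),
                          charge = integer(0), neutral_mass = numeric(0),
                          theoretical_mz = numeric(0), ppm_error = numeric(0),
                          dbe = numeric(0)))
  }
  dplyr::arrange(out, abs(.data$ppm_error), .data$formula, .data$adduct)
}

.as_adduct_tbl <- function(adducts) {
  if (is.data.frame(adducts)) {
    if (is.null(adducts$polarity)) {
      adducts$polarity <- ifelse(adducts$charge > 0, "+", "-")
    }
    return(adducts)
  }
  adduct_table(adducts)
}
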