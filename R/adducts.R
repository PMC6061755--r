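#' Electrospray adduct table
#'
#' The adduct vocabulary used for ion arithmetic, as a tibble with one row
#' per adduct: `adduct` (name), `n` (number of M units), `delta` (atoms added
#' or removed, as a signed formula string), `charge` (signed integer) and
#' `polarity`. `"[M+Formate]-"` is accepted as an alias of `"[M+HCOO]-"`.
#'
#' @param names Optional character vector restricting (and ordering) the rows;
#'   unknown names raise an error.
#' @return Tibble of adduct specifications.
#' @examples
#' adduct_table(c("[M+H]+", "[M+NH4]+"))
#' @export
adduct_table <- function(names = NULL) {
  tab <- tibble::tribble(
    ~adduct,       ~n, ~delta,  ~charge,
    "[M+H]+",      1L, "H",      1L,
    "[M+NH4]+",    1L, "NH4",    1L,
    "[M+Na]+",     1L, "Na",     1L,
    "[M+K]+",      1L, "K",      1L,
    "[M+2H]2+",    1L, "H2",     2L,
    "[2M+H]+",     2L, "H",      1L,
    "[M-H]-",      1L, "-H",    -1L,
    "[M+HCOO]-",   1L, "CHO2",  -1L,
    "[M-2H]2-",    1L, "-H2",   -2L,
    "[2M-H]-",     2L, "-H",    -1L
  )
  tab$polarity <- ifelse(tab$charge > 0, "+", "-")
  if (!is.null(names)) {
    names <- canonical_adduct(names)
    missing <- setdiff(names, tab$adduct)
    if (length(missing) > 0) {
      stop("unknown adduct name(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    tab <- tab[match(names, tab$adduct), ]
  }
  tab
}

canonical_adduct <- function(x) {
  x <- gsub("−", "-", x)                # unicode minus
  x <- gsub("Formate", "HCOO", x, fixed = TRUE)
  gsub(" ", "", x)
}

.adduct_row <- function(adduct) {
  if (is.data.frame(adduct)) {
    stopifnot(nrow(adduct) == 1)
    return(adduct)
  }
  if (is.list(adduct)) return(tibble::as_tibble(adduct))
  adduct_table(adduct)
}

# Mass of the delta formula (signed counts allowed).
delta_mass <- function(delta, elements = element_table()) {
  vapply(delta, function(d) monoisotopic_mass(parse_formula(d), elements),
         numeric(1), USE.NAMES = FALSE)
}

#' m/z of an adduct ion
#'
#' `m/z = (n * M + mass(delta) - z * m_electron) / |z|`, with the electron
#' mass included (it matters at low-ppm accuracy). Vectorized over
#' `neutral_mass`.
#'
#' @param neutral_mass Neutral monoisotopic mass(es) in Da, > 0.
#' @param adduct Adduct name (see [adduct_table()]) or a one-row adduct
#'   specification with fields `n`, `delta`, `charge`.
#' @param elements Isotope table.
#' @return m/z value(s).
#' @examples
#' adduct_mz(610.15338, "[M+H]+") # 611.16066
#' @export
adduct_mz <- function(neutral_mass, adduct, elements = element_table()) {
  stopifnot(all(neutral_mass > 0))
  a <- .adduct_row(adduct)
  if (a$charge == 0) stop("adduct charge must be nonzero", call. = FALSE)
  (a$n * neutral_mass + delta_mass(a$delta, elements) -
     a$charge * atomic_constants[["electron"]]) / abs(a$charge)
}

#' Neutral mass implied by an observed m/z under an adduct
#'
#' Inverse of [adduct_mz()].
#'
#' @param mz Observed m/z value(s).
#' @inheritParams adduct_mz
#' @return Implied neutral monoisotopic mass(es) in Da.
#' @export
neutral_mass <- function(mz, adduct, elements = element_table()) {
  a <- .adduct_row(adduct)
  if (a$charge == 0) stop("adduct charge must be nonzero", call. = FALSE)
  (abs(a$charge) * mz + a$charge * atomic_constants[["electron"]] -
     delta_mass(a$delta, elements)) / a$n
}
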