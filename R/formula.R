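#' Parse a molecular formula string
#'
#' Parses Hill-notation strings such as `"C27H30O16"` into a named integer
#' vector of element counts. A leading minus sign negates every count (used
#' internally for adduct deltas, e.g. `"-H"`).
#'
#' @param x A formula string, or an already-parsed named numeric vector
#'   (returned unchanged apart from coercion to integer counts).
#' @return Named integer vector, element symbol -> count.
#' @examples
#' parse_formula("C27H30O16")
#' @export
parse_formula <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) {
    counts <- as.integer(round(x))
    names(counts) <- names(x)
    return(counts[counts != 0])
  }
  stopifnot(is.character(x), length(x) == 1)
  s <- gsub("\\s", "", x)
  sign <- 1L
  if (startsWith(s, "-")) {
    sign <- -1L
    s <- substring(s, 2)
  }
  if (s == "") return(stats::setNames(integer(0), character(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s)) {
    stop("cannot parse formula string: '", x, "'", call. = FALSE)
  }
  els <- sub("[0-9]*$", "", toks)
  cnt <- as.integer(ifelse(grepl("[0-9]+$", toks),
                           sub("^[A-Za-z]+", "", toks), "1"))
  counts <- tapply(sign * cnt, els, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out[out != 0]
}

#' Render element counts in Hill order
#'
#' Carbon first, then hydrogen, then all other elements alphabetically
#' (the convention used for all formula output in the package). Formulas
#' without carbon are rendered fully alphabetically, per Hill's rule.
#'
#' @param counts Named integer vector or formula string.
#' @return A single formula string.
#' @examples
#' format_formula(c(O = 16, C = 27, H = 30))
#' @export
format_formula <- function(counts) {
  counts <- parse_formula(counts)
  if (length(counts) == 0) return("")
  els <- names(counts)
  if ("C" %in% els) {
    ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  } else {
    ord <- sort(els)
  }
  counts <- counts[ord]
  paste0(names(counts), ifelse(counts == 1, "", counts), collapse = "")
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of principal-isotope masses (most abundant isotope per element,
#' the standard monoisotopic convention). Vectorized over formula strings.
#'
#' @param formula Character vector of formula strings (or one named count
#'   vector). Counts may be negative for adduct deltas.
#' @param elements Isotope table, see [element_table()].
#' @return Numeric vector of masses in Da. The empty formula has mass 0.
#' @examples
#' monoisotopic_mass("C27H30O16") # rutin, 610.15338
#' @export
monoisotopic_mass <- function(formula, elements = element_table()) {
  pm <- principal_masses(elements)
  one <- function(f) {
    counts <- parse_formula(f)
    if (length(counts) == 0) return(0)
    unknown <- setdiff(names(counts), names(pm))
    if (length(unknown) > 0) {
      stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    sum(counts * pm[names(counts)])
  }
  if (is.numeric(formula)) return(one(formula))
  vapply(formula, one, numeric(1), USE.NAMES = FALSE)
}

# Valence classes for the DBE formula: halogens count as H, P counts as N,
# divalent O and S contribute zero.
.dbe_h_like <- c("H", "F", "Cl", "Br", "I")
.dbe_n_like <- c("N", "P")
.dbe_zero <- c("O", "S")

#' Ring-and-double-bond equivalents (DBE)
#'
#' DBE = nC - (nH + nHalogen)/2 + (nN + nP)/2 + 1. Elements outside the
#' valence table (C, H, N, O, S, P, halogens) contribute 0 with a warning.
#' Vectorized over formula strings.
#'
#' @inheritParams monoisotopic_mass
#' @return Numeric vector of DBE values.
#' @examples
#' dbe("C48H76O18") # 11
#' dbe("C48H78O17") # 10
#' @export
dbe <- function(formula) {
  one <- function(f) {
    counts <- parse_formula(f)
    known <- c("C", .dbe_h_like, .dbe_n_like, .dbe_zero)
    extra <- setdiff(names(counts), known)
    if (length(extra) > 0) {
      warning("element(s) outside the DBE valence table contribute 0: ",
              paste(extra, collapse = ", "), call. = FALSE)
    }
    g <- function(set) sum(counts[intersect(names(counts), set)])
    g("C") - g(.dbe_h_like) / 2 + g(.dbe_n_like) / 2 + 1
  }
  if (is.numeric(formula)) return(one(formula))
  vapply(formula, one, numeric(1), USE.NAMES = FALSE)
}
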