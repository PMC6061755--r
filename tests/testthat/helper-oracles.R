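# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the package implementation.

# All nonnegative integer k-vectors summing to n (isotope compositions).
compositions <- function(n, k) {
  if (k == 1) return(matrix(n, ncol = 1))
  out <- list()
  for (i in 0:n) {
    sub <- compositions(n - i, k - 1)
    out[[length(out) + 1]] <- cbind(i, sub)
  }
  do.call(rbind, out)
}

# Brute-force isotope envelope by direct polynomial expansion: enumerate
# every per-element isotope composition, multiply multinomial
# probabilities across elements, and aggregate at nucleon resolution.
oracle_isotope_pattern <- function(formula, elements = element_table()) {
  counts <- parse_formula(formula)
  per_el <- lapply(names(counts), function(el) {
    iso <- elements[elements$element == el, ]
    comp <- compositions(counts[[el]], nrow(iso))
    data.frame(
      prob = apply(comp, 1, function(x) dmultinom(x, prob = iso$abundance)),
      mass = as.vector(comp %*% iso$mass),
      offset = as.vector(comp %*% iso$offset))
  })
  grid <- do.call(expand.grid, lapply(per_el, function(d) seq_len(nrow(d))))
  prob <- rep(1, nrow(grid)); mass <- rep(0, nrow(grid)); off <- rep(0L, nrow(grid))
  for (j in seq_along(per_el)) {
    d <- per_el[[j]][grid[[j]], ]
    prob <- prob * d$prob
    mass <- mass + d$mass
    off <- off + d$offset
  }
  agg_p <- tapply(prob, off, sum)
  agg_m <- tapply(prob * mass, off, sum) / agg_p
  data.frame(offset = as.integer(names(agg_p)),
             mass = as.vector(agg_m),
             abundance = 100 * as.vector(agg_p) / max(agg_p))
}

# Nested-loop formula enumeration with early mass pruning, written as
# plain loops over CHNO counts; same chemical filters, different search.
oracle_enumerate <- function(mz, adduct_name, bounds_max = c(C = 30, H = 60,
                                                            N = 3, O = 15),
                             tol_ppm = 5) {
  a <- adduct_table(adduct_name)
  el <- element_table()
  pm <- c(C = el$mass[el$element == "C"][1], H = el$mass[el$element == "H"][1],
          N = el$mass[el$element == "N"][1], O = el$mass[el$element == "O"][1])
  target <- (abs(a$charge) * mz + a$charge * atomic_constants[["electron"]] -
               monoisotopic_mass(a$delta)) / a$n
  tol <- target * tol_ppm * 1e-6
  hits <- character(0)
  for (nc in 0:bounds_max[["C"]]) {
    mc <- nc * pm[["C"]]
    if (mc > target + tol) break
    for (nn in 0:bounds_max[["N"]]) {
      mn <- mc + nn * pm[["N"]]
      if (mn > target + tol) break
      for (no in 0:bounds_max[["O"]]) {
        mo <- mn + no * pm[["O"]]
        if (mo > target + tol) break
        for (nh in 0:bounds_max[["H"]]) {
          m <- mo + nh * pm[["H"]]
          if (m > target + tol) break
          if (abs(m - target) > tol) next
          d <- nc - nh / 2 + nn / 2 + 1
          if (d < 0 || abs(d - round(d)) > 1e-9) next
          if (nh > 2 * nc + nn + 2) next
          nominal <- 12 * nc + nh + 14 * nn + 16 * no
          if ((nominal %% 2 == 0) != (nn %% 2 == 0)) next
          v <- c(C = nc, H = nh, N = nn, O = no)
          hits <- c(hits, format_formula(v[v > 0]))
        }
      }
    }
  }
  sort(hits)
}

# Dense-grid USP metrics on the analytic EMG, written independently of
# the package's peak machinery (inline EMG expression, dt = 1e-4 min).
oracle_emg_usp <- function(mu, sigma, tau, dt = 1e-4, span = 3) {
  t <- seq(mu - span - 5 * sigma, mu + span + 5 * sigma, by = dt)
  y <- if (tau > 1e-12) {
    z <- (sigma / tau - (t - mu) / sigma) / sqrt(2)
    ifelse(z < 25,
           1 / (2 * tau) * exp(sigma^2 / (2 * tau^2) - (t - mu) / tau) *
             pracma::erfc(z),
           1 / (2 * tau) * exp(-(t - mu)^2 / (2 * sigma^2)) *
             (1 - 0.5 / z^2) / (z * sqrt(pi)))
  } else {
    exp(-(t - mu)^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
  }
  ia <- which.max(y)
  h <- y[ia]
  crossing <- function(frac, side) {
    thr <- frac * h
    if (side == "left") {
      j <- max(which(y[1:ia] < thr))
      t[j] + dt * (thr - y[j]) / (y[j + 1] - y[j])
    } else {
      j <- ia - 1 + min(which(y[ia:length(y)] < thr))
      t[j - 1] + dt * (y[j - 1] - thr) / (y[j - 1] - y[j])
    }
  }
  a10 <- t[ia] - crossing(0.10, "left"); b10 <- crossing(0.10, "right") - t[ia]
  a5 <- t[ia] - crossing(0.05, "left"); b5 <- crossing(0.05, "right") - t[ia]
  list(asymmetry = b10 / a10, tailing = (a5 + b5) / (2 * a5))
}

# Small random CHNO formulas with <= `max_atoms` atoms total (for the
# isotope-oracle comparison).
random_small_formulas <- function(n, max_atoms = 40) {
  out <- character(n)
  i <- 0
  while (i < n) {
    v <- c(C = sample(1:15, 1), H = sample(0:20, 1), N = sample(0:3, 1),
           O = sample(0:6, 1))
    if (sum(v) > max_atoms) next
    i <- i + 1
    out[i] <- format_formula(v[v > 0])
  }
  out
}

# Five-constituent synthetic extract shared by several tests.
demo_constituents <- function() {
  tibble::tibble(
    name = c("rutin", "quercetin", "ginkgolide A", "kaempferol", "bilobalide"),
    formula = c("C27H30O16", "C15H10O7", "C20H24O9", "C15H10O6", "C15H18O8"),
    rt = c(3, 5, 7, 9, 11),
    fraction = c(40, 25, 15, 12, 8),
    adducts_pos = c("[M+H]+;[M+NH4]+", "[M+H]+", "[M+H]+;[M+NH4]+",
                    "[M+H]+", "[M+H]+"),
    adducts_neg = c("[M-H]-", "[M-H]-", "[M-H]-;[M+HCOO]-", "[M-H]-",
                    "[M-H]-"))
}
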