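simple_spectra <- function(mzs, intensities, rts, polarity = "+") {
  purrr::map_dfr(seq_along(rts), function(i) {
    tibble::tibble(scan = i, rt = rts[i], polarity = polarity,
                   mz = mzs, intensity = intensities[[i]])
  }) |> dplyr::filter(.data$intensity > 0)
}

test_that("EIC sums centroids inside the ppm window and zeros elsewhere", {
  rts <- seq(0, 1, by = 0.01)
  sp <- simple_spectra(500, lapply(seq_along(rts), function(i) i), rts)
  eic <- extract_eic(sp, 500, tol_ppm = 10)
  expect_equal(eic$intensity, seq_along(rts))
  # a centroid offset by twice the tolerance contributes nothing
  off <- extract_eic(sp, 500 * (1 + 20e-6), tol_ppm = 10)
  expect_equal(off$intensity, rep(0, length(rts)))
  expect_error(extract_eic(sp, 500, tol_ppm = 0), "positive")
})

test_that("EIC apex matches simulated elution within one scan interval", {
  cons <- tibble::tibble(name = "rutin", formula = "C27H30O16", rt = 2,
                         fraction = 100, tau = 0)
  sx <- simulate_extract(cons, simulation_config(seed = 9))
  mz0 <- adduct_mz(monoisotopic_mass("C27H30O16"), "[M+H]+")
  eic <- extract_eic(sx$spectra, mz0)
  scan_dt <- 1 / (60 * 5)
  expect_lt(abs(eic$time[which.max(eic$intensity)] - 2), scan_dt + 1e-9)
  # noiseless EIC area integrates to the generated trace area within 1%
  feat <- detect_features(sx$spectra)
  mono <- feat[which.min(abs(feat$mz - mz0)), ]
  expect_equal(mono$area, pracma::trapz(eic$time, eic$intensity),
               tolerance = 0.01)
})

test_that("co-apexing traces spaced by 1.00336/z merge into one feature", {
  rts <- seq(0, 0.2, by = 1 / 300)
  shape <- exp(-(rts - 0.1)^2 / (2 * 0.03^2))
  z1 <- simple_spectra(c(611.1607, 612.1641),
                       lapply(shape, function(s) c(1000, 300) * s), rts)
  f1 <- detect_features(z1)
  expect_equal(nrow(f1), 1)
  expect_equal(f1$charge, 1)
  expect_equal(nrow(f1$envelope[[1]]), 2)
  expect_equal(f1$mz, 611.1607, tolerance = 1e-4)

  z2 <- simple_spectra(c(749.2000, 749.2000 + 1.00336 / 2),
                       lapply(shape, function(s) c(1000, 800) * s), rts)
  f2 <- detect_features(z2)
  expect_equal(nrow(f2), 1)
  expect_equal(f2$charge, 2)

  iso <- simple_spectra(321.1, lapply(shape, function(s) 500 * s), rts)
  f3 <- detect_features(iso)
  expect_equal(nrow(f3), 1)
  expect_equal(f3$charge, 1)
  expect_equal(nrow(f3$envelope[[1]]), 1)
})

test_that("an ion trace needs at least min_scans consecutive scans", {
  rts <- seq(0, 0.2, by = 1 / 300)
  two_scans <- simple_spectra(400, lapply(seq_along(rts), function(i) {
    if (i %in% c(10, 11)) 1000 else 0
  }), rts)
  expect_equal(nrow(detect_features(two_scans, min_scans = 3)), 0)
  expect_equal(nrow(detect_features(two_scans, min_scans = 2)), 1)
})

test_that("dense profile-like spectra are rejected", {
  raster <- tibble::tibble(scan = 1, rt = 0.5, polarity = "+",
                           mz = seq(100, 101, by = 0.001),
                           intensity = 10)
  expect_error(detect_features(raster), "centroid")
})

test_that("adduct relations merge features into one neutral analyte", {
  rts <- seq(0, 0.2, by = 1 / 300)
  shape <- exp(-(rts - 0.1)^2 / (2 * 0.03^2))
  m <- monoisotopic_mass("C27H30O16")
  sp <- simple_spectra(c(adduct_mz(m, "[M+H]+"), adduct_mz(m, "[M+NH4]+")),
                       lapply(shape, function(s) c(1000, 400) * s), rts)
  g <- group_adducts(detect_features(sp))
  expect_equal(nrow(g), 1)
  expect_equal(g$neutral_mass, m, tolerance = m * 1e-5)
  expect_setequal(g$members[[1]]$adduct, c("[M+H]+", "[M+NH4]+"))

  # mass-unrelated features stay separate singleton groups
  sp2 <- simple_spectra(c(401.0, 455.3),
                        lapply(shape, function(s) c(1000, 400) * s), rts)
  g2 <- group_adducts(detect_features(sp2))
  expect_equal(nrow(g2), 2)
  expect_true(all(g2$members[[1]]$adduct == "[M+H]+"))
})

test_that("doubly and singly charged ions of one analyte group together", {
  rts <- seq(0, 0.2, by = 1 / 300)
  shape <- exp(-(rts - 0.1)^2 / (2 * 0.03^2))
  m <- 1496.38541
  mz2 <- adduct_mz(m, "[M+2H]2+")
  # the doubly charged ion carries its A+1 satellite at 1.00336/2 spacing
  # (charge evidence); the singly charged ion is a bare trace
  sp <- simple_spectra(c(mz2, mz2 + 1.00336 / 2, adduct_mz(m, "[M+H]+")),
                       lapply(shape, function(s) c(1000, 780, 400) * s), rts)
  feats <- detect_features(sp)
  expect_equal(nrow(feats), 2)
  expect_setequal(feats$charge, c(1, 2))
  g <- group_adducts(feats)
  expect_equal(nrow(g), 1)
  expect_equal(g$neutral_mass, m, tolerance = m * 1e-5)
})

test_that("every feature lands in exactly one group (partition)", {
  set.seed(707)
  cons <- demo_constituents()
  sx <- simulate_extract(cons, simulation_config(seed = 707))
  feats <- detect_features(sx$spectra)
  g <- group_adducts(feats)
  member_ids <- sort(unlist(purrr::map(g$members, "feature")))
  expect_equal(member_ids, sort(feats$feature))
  expect_equal(sum(g$n_members), nrow(feats))
})

test_that("groups recover the generating analytes and neutral masses", {
  cons <- demo_constituents()
  sx <- simulate_extract(cons, simulation_config(seed = 708))
  g <- group_adducts(detect_features(sx$spectra))
  expect_equal(nrow(g), nrow(cons))
  got <- sort(g$neutral_mass)
  want <- sort(monoisotopic_mass(cons$formula))
  expect_equal(got, want, tolerance = 1e-5)
  expect_true(all(abs(g$rt[order(g$neutral_mass)] -
                        cons$rt[order(monoisotopic_mass(cons$formula))]) <
                    0.06))
})

test_that("spectra round-trip through JSON and mzML", {
  cons <- demo_constituents()[1:2, ]
  cons$fraction <- c(60, 40)
  sx <- simulate_extract(cons, simulation_config(seed = 5))
  jf <- withr::local_tempfile(fileext = ".json")
  write_spectra(sx$spectra, jf)
  back <- read_spectra(jf)
  expect_equal(nrow(back), nrow(sx$spectra))
  expect_equal(sort(back$mz), sort(sx$spectra$mz), tolerance = 1e-12)

  mf <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(sx$spectra, mf, polarity = "+")
  pos <- dplyr::filter(sx$spectra, .data$polarity == "+")
  back2 <- read_spectra(mf)
  expect_equal(nrow(back2), nrow(pos))
  expect_equal(sort(back2$mz), sort(pos$mz), tolerance = 1e-9)
  expect_true(all(back2$polarity == "+"))
  expect_equal(sort(unique(back2$rt)), sort(unique(pos$rt)),
               tolerance = 1e-9)
})
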