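demo_report <- function(seed = 11) {
  cons <- demo_constituents()
  sx <- simulate_extract(cons, simulation_config(seed = seed))
  std <- tibble::tibble(name = "Rutin", formula = "C27H30O16", rt = 3.02,
                        cas = "153-18-4")
  ann <- tibble::tibble(formula = "C15H10O7", name = "Quercetin",
                        cas = "117-39-5", annotation = "flavonol aglycone")
  run_pipeline(sx$cad, sx$spectra, standards = std, annotations = ann)
}

test_that("empty inputs give an empty report", {
  rep0 <- build_report(tibble::tibble(peak = integer(0)),
                       tibble::tibble(peak = integer(0)))
  expect_s3_class(rep0, "extract_report")
  expect_equal(rep0$summary$n_peaks, 0)
  expect_equal(unknown_summary(rep0)$total_unidentified_percent, 0)
})

test_that("peak-number mismatches error listing the orphans", {
  quant <- tibble::tibble(peak = 1:3, cad_percent = c(50, 30, 20))
  assignments <- tibble::tibble(peak = c(1L, 2L), n_analytes = 1L,
                                coelution = FALSE, low_level_extra = FALSE,
                                groups = list(NULL, NULL))
  expect_error(build_report(assignments, quant), "orphans: 3")
})

test_that("the pipeline report names analytes and conserves percentages", {
  rep <- demo_report()
  rec <- tidy(rep)
  expect_equal(nrow(rec), 5)
  expect_equal(sum(rec$cad_percent), 100, tolerance = 1e-9)
  expect_equal(rec$proposed_id[1], "Rutin")
  expect_equal(rec$tier[1], "standard_match")
  expect_equal(rec$tier[2], "proposed")
  expect_true(all(rec$tier[3:5] == "formula_only"))
  # top-ranked formulas match the generating constituents
  expect_equal(rec$formula,
               c("C27H30O16", "C15H10O7", "C20H24O9", "C15H10O6",
                 "C15H18O8"))
  expect_equal(rec$cad_percent, demo_constituents()$fraction,
               tolerance = 0.02)
  g <- glance(rep)
  expect_equal(g$n_peaks, 5L)
})

test_that("unknown summary follows the tier interpretation switch", {
  rep <- demo_report()
  u <- unknown_summary(rep)
  # three formula-only unknowns: 15 + 12 + 8
  expect_equal(u$total_unidentified_percent, 35, tolerance = 0.1)
  expect_equal(u$max_unknown_percent, 15, tolerance = 0.1)
  flipped <- unknown_summary(rep, count_formula_only_as_identified = TRUE)
  expect_equal(flipped$total_unidentified_percent, 0)
  # removing an identification can only raise both statistics
  rep2 <- rep
  rep2$records$proposed_id[2] <- "Unknown"
  rep2$records$tier[2] <- "formula_only"
  u2 <- unknown_summary(rep2)
  expect_gte(u2$total_unidentified_percent, u$total_unidentified_percent)
  expect_gte(u2$max_unknown_percent, u$max_unknown_percent)
})

test_that("MS-only analytes appear as below-floor entries", {
  cons <- demo_constituents()
  # simulate normally, then add an MS-only group eluting far from any
  # CAD peak (an analyte the MS sees but the CAD does not)
  sx <- simulate_extract(cons, simulation_config(seed = 21))
  tr <- estimate_baseline(sx$cad)
  peaks <- detect_peaks(tr)
  quant <- relative_quantitation(peaks)
  g <- group_adducts(detect_features(sx$spectra))
  extra <- g[1, ]
  extra$group <- max(g$group) + 1L
  extra$rt <- max(peaks$rt_right) + 5
  g2 <- dplyr::bind_rows(g, extra)
  g2 <- annotate_groups(g2)
  assigned <- assign_groups_to_peaks(peaks, g2)
  expect_equal(sum(assigned$below_floor), 1)
  rep <- build_report(peak_assignments(peaks, assigned), quant,
                      below_floor = dplyr::filter(assigned,
                                                  .data$below_floor),
                      floor = 0.05)
  expect_equal(nrow(rep$below_floor), 1)
  expect_equal(rep$below_floor$flag, "< 0.05%")
})

test_that("identical seed and config give byte-identical report JSON", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cons <- demo_constituents()
  for (d in c(d1, d2)) {
    sx <- simulate_extract(cons, simulation_config(seed = 33))
    run_pipeline(sx$cad, sx$spectra, out_dir = d)
  }
  j1 <- readBin(file.path(d1, "report.json"), "raw",
                file.size(file.path(d1, "report.json")))
  j2 <- readBin(file.path(d2, "report.json"), "raw",
                file.size(file.path(d2, "report.json")))
  expect_identical(j1, j2)
})

test_that("artifacts are written and config errors surface with stage names", {
  d <- withr::local_tempdir()
  cons <- demo_constituents()
  sx <- simulate_extract(cons, simulation_config(seed = 34))
  rep <- run_pipeline(sx$cad, sx$spectra, out_dir = d)
  expect_setequal(list.files(d), c("peaks.csv", "features.csv",
                                   "report.csv", "report.json",
                                   "config.json"))
  rec <- utils::read.csv(file.path(d, "report.csv"))
  expect_equal(nrow(rec), nrow(tidy(rep)))
  cfg <- botanicad_config()
  cfg$chromatogram$min_rel_area <- 60   # floor above every peak
  expect_error(run_pipeline(sx$cad, sx$spectra, config = cfg),
               "detect_peaks")
})

test_that("yaml config merges over defaults", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("chromatogram:", "  min_snr: 5", "ms:", "  tol_ppm: 7"), f)
  cfg <- read_config(f)
  expect_equal(cfg$chromatogram$min_snr, 5)
  expect_equal(cfg$ms$tol_ppm, 7)
  expect_equal(cfg$chromatogram$min_rel_area, 0.05)   # untouched default
})

test_that("report plots build", {
  rep <- demo_report()
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
  cons <- demo_constituents()
  sx <- simulate_extract(cons, simulation_config(seed = 11))
  tr <- estimate_baseline(sx$cad)
  p2 <- plot_chromatogram(tr, detect_peaks(tr))
  expect_s3_class(p2, "ggplot")
  pat <- isotope_pattern("C27H30O16", adduct = "[M+H]+")
  p3 <- plot_isotope_fit(observed_envelope(pat$mz[1:3], pat$abundance[1:3]),
                         "C27H30O16", "[M+H]+")
  expect_s3_class(p3, "ggplot")
})
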