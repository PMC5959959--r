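# Synthetic cohorts, cases, calibration batches and instrument rendering.

test_that("cohort simulation is deterministic and leaves RNG state alone", {
  panel <- oa_test_panel()
  spec <- cohort_spec(panel, n_per_group = c("0-2y" = 3, ">2y" = 3))
  a <- simulate_cohort(spec, seed = 5)
  b <- simulate_cohort(spec, seed = 5)
  expect_equal(a, b)
  set.seed(99)
  expected_next <- rnorm(1)
  set.seed(99)
  invisible(simulate_cohort(spec, seed = 5))
  expect_identical(rnorm(1), expected_next)
})

test_that("degenerate spread collapses samples onto the geometric mean", {
  panel <- oa_test_panel()
  spec <- cohort_spec(panel, n_per_group = c(">2y" = 4), sd_log2 = 1e-9)
  coh <- simulate_cohort(spec, seed = 2)
  lac <- coh[coh$analyte == "Lactic acid", ]
  gm <- 2^spec$analytes$mean_log2[spec$analytes$analyte == "Lactic acid" &
                                    spec$analytes$age_group == ">2y"]
  expect_equal(lac$conc_norm, rep(gm, 4), tolerance = 1e-6)
})

test_that("unit fold-changes reproduce the matched control draw", {
  panel <- oa_test_panel()
  spec <- cohort_spec(panel, n_per_group = c("0-2y" = 2, ">2y" = 2))
  null_case <- case_spec("null", c("Glutaric acid" = 1))
  case <- simulate_case(null_case, spec, age_group = "0-2y", seed = 8,
                        sample_id = "x")
  ctrl_spec <- spec
  ctrl_spec$n_per_group <- c("0-2y" = 1)
  ctrl <- simulate_cohort(ctrl_spec, seed = 8, prefix = "x")
  expect_equal(case$conc_norm, ctrl$conc_norm)
  expect_error(simulate_case(case_spec("bad", c("Unobtainium" = 2)), spec),
               class = "oa_synth_error")
})

test_that("case biomarkers clear the significance threshold end to end", {
  panel <- oa_test_panel()
  spec <- cohort_spec(panel)
  coh <- simulate_cohort(spec, seed = 14)
  ref <- build_reference(coh, spec_lods(spec))
  mcadd <- simulate_case(iem_case_library()$MCADD, spec, seed = 4)
  prof <- profile_sample(mcadd, ref)
  bm <- names(iem_case_library()$MCADD$biomarkers)
  expect_true(all(prof$z[match(bm, prof$analyte)] > 5))
  expect_true(all(prof$flag[match(bm, prof$analyte)] == "elevated"))
})

test_that("5-oxoprolinuria case carries no paracetamol markers", {
  panel <- oa_test_panel()
  spec <- cohort_spec(panel)
  coh <- simulate_cohort(spec, seed = 14)
  ref <- build_reference(coh, spec_lods(spec))
  oxo <- simulate_case(iem_case_library()$`5-oxoprolinuria`, spec, seed = 6)
  prof <- profile_sample(oxo, ref)
  expect_gt(prof$z[prof$analyte == "Pyroglutamic acid"], 3)
  med <- c("Acetaminophen glucuronide", "Acetaminophensulphate")
  expect_equal(prof$z[match(med, prof$analyte)], c(0, 0))
  # and a medicated sample does show them
  medded <- simulate_case(
    case_spec("paracetamol user", c("Pyroglutamic acid" = 3),
              medication = med),
    spec, seed = 6)
  prof2 <- profile_sample(medded, ref)
  expect_true(all(prof2$z[match(med, prof2$analyte)] > 3))
})

test_that("simulated calibration batches stay linear at 5% noise", {
  panel <- oa_test_panel()
  sim <- simulate_calibration_ratios(panel, cv = 0.05, seed = 1)
  expect_identical(dplyr::n_distinct(sim$analyte), 68L)
  expect_identical(nrow(sim), 68L * 6L)
  fits <- sim |>
    dplyr::group_by(.data$analyte) |>
    dplyr::group_modify(~ glance(fit_calibration(.x))[-1]) |>
    dplyr::ungroup()
  expect_gte(min(fits$r.squared), 0.98)
  # noise-free ratios reproduce the generating slope exactly
  clean <- simulate_calibration_ratios(panel, cv = 0, seed = 1)
  one <- clean[clean$analyte == "Glutaric acid", ]
  cc <- fit_calibration(one)
  expect_equal(cc$slope, one$true_slope[1])
  expect_equal(cc$r2, 1)
})

test_that("rendered blanks contain internal standards only", {
  panel <- oa_mini_panel()
  blank <- tibble::tibble(sample_id = "bl", sample_type = "blank",
                          dilution_factor = 1, creatinine = NA_real_,
                          analyte = NA_character_, conc_injected = NA_real_)
  rend <- render_instrument_data(blank, panel, instrument_model(panel),
                                 seed = 2)
  m <- measure_sample(rend$peaklists$bl, panel)
  expect_identical(sum(m$found[m$kind == "analyte"]), 0L)
  expect_identical(sum(m$found[m$kind == "istd"]), nrow(panel$istds))
})

test_that("noise-free rendering round-trips concentrations within 0.5%", {
  panel <- oa_mini_panel()
  spec <- cohort_spec(panel, n_per_group = c(">2y" = 2))
  coh <- simulate_cohort(spec, seed = 10)
  truths <- dplyr::bind_rows(
    patient_truths(coh),
    calibrant_truths(panel)[1:6])
  rend <- render_instrument_data(truths, panel, instrument_model(panel),
                                 seed = 3)
  res <- process_batch(rend$peaklists, rend$manifest, panel,
                       calibrant_truths(panel))
  chk <- res$quants |>
    dplyr::inner_join(coh, by = c("sample_id", "analyte")) |>
    dplyr::filter(.data$conc_norm.y > 0, !.data$below_lod.y)
  rel <- abs(chk$conc_norm.x - chk$conc_norm.y) / chk$conc_norm.y
  expect_gt(nrow(chk), 4)
  expect_lt(max(rel), 0.005)
})

test_that("written peak-list batches reload through the manifest", {
  panel <- oa_mini_panel()
  out <- withr::local_tempdir()
  truth <- tibble::tibble(
    sample_id = "s1", sample_type = "patient", dilution_factor = 16,
    creatinine = 4, analyte = "Lactic acid", conc_injected = 12)
  rend <- render_instrument_data(truth, panel, instrument_model(panel),
                                 seed = 1, out_dir = out)
  expect_true(file.exists(file.path(out, "s1.tsv")))
  expect_true(file.exists(file.path(out, "manifest.csv")))
  pk <- read_peaklist(file.path(out, "s1.tsv"))
  expect_equal(pk, rend$peaklists$s1)
})
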