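gallic <- calibrationCurve(0.005, 0, c(10, 300), "gallic acid")

test_that("Folin-type unit chain matches hand arithmetic", {
  # 100 ug/mL read, DF 1, 30 mL extract, 5 g sample:
  # 3000 ug in extract = 3 mg per 5 g = 60 mg/100 g
  expect_equal(quantifyFolin(0.005 * 100, gallic, 1, 5, 30, warn = FALSE), 60)
  # zero response at the intercept
  expect_equal(quantifyFolin(gallic@intercept, gallic, 1, 5, 30, warn = FALSE), 0)
  # linear in absorbance above the intercept and in the dilution factor
  a <- 0.25
  expect_equal(quantifyFolin(2 * a, gallic, 1, 5, 30, warn = FALSE),
               2 * quantifyFolin(a, gallic, 1, 5, 30, warn = FALSE))
  expect_equal(quantifyFolin(a, gallic, 10, 5, 30, warn = FALSE),
               10 * quantifyFolin(a, gallic, 1, 5, 30, warn = FALSE))
  expect_error(quantifyFolin(a, gallic, 0.5), ">= 1")
})

test_that("pH-differential anthocyanin formula matches hand arithmetic", {
  # A = 0.5, DF 10 -> 0.5 * 449.2 * 10 * 1000 / 26900 = 83.494 mg/L
  # -> x 0.030 L x (100/5 g) = 50.10 mg/100 g FW
  v <- quantifyTAC(0.55, 0.02, 0.06, 0.03, 10, 5, 30)
  expect_equal(v, 0.5 * 449.2 * 10 * 1000 / 26900 * 0.030 * 20,
               tolerance = 1e-12)
  expect_equal(round(v, 2), 50.1)
  # zero differential absorbance
  expect_equal(quantifyTAC(0.05, 0.02, 0.06, 0.03), 0)
  # negative differential clamps to zero with a warning
  expect_warning(v0 <- quantifyTAC(0.04, 0.02, 0.06, 0.03), "clamped")
  expect_equal(v0, 0)
  expect_error(quantifyTAC(0.5, NA, 0.06, 0.03), "four")
})

test_that("FRAP unit chain matches hand arithmetic", {
  tro <- calibrationCurve(1, 0, c(0, 10), "Trolox")
  # 0.5 mM read x DF 2 = 1 mM extract; x 30 mL = 30 umol per 5 g = 6 umol/g
  expect_equal(quantifyFRAP(0.5, tro, 2, 5, 30, warn = FALSE), 6)
  expect_equal(quantifyFRAP(tro@intercept, tro, 2, 5, 30, warn = FALSE), 0)
})

test_that("ABTS inhibition, flags and blank check behave per contract", {
  expect_equal(abtsInhibition(0.35, 0.70), 50)
  expect_equal(abtsInhibition(0.70, 0.70), 0)
  expect_error(abtsInhibition(0.1, 0), "> 0")
  tro <- calibrationCurve(80, 0, c(0.05, 1), "Trolox")
  v <- quantifyABTS(0.35, 0.70, tro, 10, 5, 30, warn = FALSE)
  expect_equal(as.numeric(v), 50 / 80 * 10 * 30 / 5)
  expect_identical(attr(v, "flag"), "")
  # no inhibition: flagged out of the 20-80% window, not rejected
  v0 <- quantifyABTS(0.70, 0.70, tro, 10, 5, 30, warn = FALSE)
  expect_identical(attr(v0, "flag"), "inhibition_out_of_range")
  # drifted working solution triggers a configuration warning
  expect_warning(quantifyABTS(0.40, 0.75, tro, 10, 5, 30, warn = FALSE),
                 "0.70")
})

test_that("fresh-to-dry weight conversion follows the dry-matter fraction", {
  # 352.7 mg/100 g FW at 18.4% dry matter -> 3.527/0.184 = 19.17 mg/g DW
  expect_equal(round(fwToDw(352.7, 0.184), 2), 19.17)
  expect_equal(fwToDw(0, 0.15), 0)
  expect_equal(fwToDw(30, 0.15, per100g = FALSE), 200)
  expect_error(fwToDw(10, 1), "inside \\(0, 1\\)")
  expect_error(fwToDw(10, 0), "inside \\(0, 1\\)")
})

test_that("table-level quantification dispatches by assay and errors on junk", {
  abs <- data.frame(
    genotype = "g1", assay = c("TPC", "ABTS", "ABTS"), replicate = 1L,
    reading_name = c("A760", "A734_sample", "A734_blank"),
    value = c(0.31, 0.35, 0.70), dilution_factor = c(10, 10, 10))
  ctx <- data.frame(genotype = "g1", sample_mass_g = 5, extract_volume_ml = 30)
  q <- quantifyAssays(abs, ctx)
  expect_setequal(q$assay, c("TPC", "ABTS"))
  expect_true(all(q$basis == "FW"))
  expect_equal(q$value[q$assay == "TPC"],
               quantifyFolin(0.31, defaultCurves()$gallic_acid, 10, 5, 30))
  bad <- abs; bad$assay <- "XYZ"
  expect_error(quantifyAssays(bad, ctx), "unknown assay")
  expect_error(quantifyAssays(abs, ctx[, 1:2]), "context")
})

test_that("DW basis rebases values and units", {
  abs <- data.frame(genotype = "g1", assay = "TPC", replicate = 1L,
                    reading_name = "A760", value = 0.31,
                    dilution_factor = 10)
  ctx <- data.frame(genotype = "g1", sample_mass_g = 5,
                    extract_volume_ml = 30, dry_matter_fraction = 0.15)
  qfw <- quantifyAssays(abs, ctx)
  qdw <- quantifyAssays(abs, ctx, basis = "DW")
  expect_equal(qdw$value, qfw$value / 100 / 0.15)
  expect_match(qdw$units, "g DW")
  expect_error(quantifyAssays(abs, ctx[, 1:3], basis = "DW"),
               "dry_matter_fraction")
})
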