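test_that("JSON records round-trip through the documented schema", {
  f <- withr::local_tempfile(fileext = ".json")
  writeTwoEyeJSON(f)
  sets <- parseRecords(f)
  expect_length(sets, 2)
  expect_equal(vapply(sets, eyeId, character(1)), c("E1", "E2"))
  expect_true(all(vapply(sets, function(s) nrow(s@scans), integer(1)) == 3))
  # unknown fields preserved opaquely
  expect_equal(sets[[1]]@metadata$site, "unit-test")
})

test_that("CSV parsing flags missing cells as missing, never zero", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "eye_id,laterality,order,k1_D,k2_D,kmax_D,cct_um,axial_length_mm,acd_mm",
    "E1,OD,1,43.0,44.0,45.0,,24.1,3.2",
    "E1,OD,2,43.1,44.1,45.1,538,24.1,3.2"), f)
  sets <- parseRecords(f)
  expect_length(sets, 1)
  expect_true(is.na(sets[[1]]@scans$cct_um[1]))
  expect_equal(sets[[1]]@scans$cct_um[2], 538)
})

test_that("duplicate acquisition order is rejected naming the eye", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "eye_id,laterality,order,k1_D,k2_D,kmax_D,cct_um,axial_length_mm,acd_mm",
    "E9,OD,1,43.0,44.0,45.0,540,24.1,3.2",
    "E9,OD,1,43.1,44.1,45.1,538,24.1,3.2"), f)
  expect_error(parseRecords(f), "E9")
  fj <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(list(eye_id = "E7", laterality = "OD",
    scans = list(list(order = 1, k1_D = 43), list(order = 1, k1_D = 43.2)))),
    fj, auto_unbox = TRUE)
  expect_error(parseRecords(fj), "E7")
})

test_that("malformed files raise schema errors naming record and field", {
  fj <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(list(laterality = "OD")), fj, auto_unbox = TRUE)
  expect_error(parseRecords(fj), "eye_id")
  fc <- withr::local_tempfile(fileext = ".csv")
  writeLines("foo,bar\n1,2", fc)
  expect_error(parseRecords(fc), "eye_id")
  expect_error(parseRecords("no/such/file.json"), "not found")
})

test_that("scan aggregation takes per-parameter medians and rejects outliers", {
  mk <- function(k1s) ScanSet("E1", "OD", data.frame(
    order = seq_along(k1s), k1_D = k1s, k2_D = k1s + 1, kmax_D = k1s + 2,
    cct_um = 540, axial_length_mm = 24.1, acd_mm = 3.2))
  expect_equal(aggregateScans(mk(c(43.0, 43.2, 43.1)))@k1_D, 43.1)
  # a single outlying acquisition does not move the median
  expect_equal(aggregateScans(mk(c(43.0, 43.1, 49.0)))@k1_D, 43.1)
  # three identical scans reproduce the scan verbatim
  r <- aggregateScans(mk(c(43.5, 43.5, 43.5)))
  expect_equal(r@k1_D, 43.5)
  expect_equal(r@k2_D, 44.5)
  expect_equal(r@astigmatism_D, 1.0)
})

test_that("aggregation is permutation-invariant and median-selects for odd k", {
  base <- data.frame(order = 1:3, k1_D = c(42.8, 43.4, 43.1),
                     k2_D = c(44.2, 44.0, 44.5), kmax_D = c(46.1, 45.8, 46.4),
                     cct_um = c(530, 534, 528), axial_length_mm = c(24.1, 24.2, 24.0),
                     acd_mm = c(3.1, 3.3, 3.2))
  r1 <- aggregateScans(ScanSet("E1", "OD", base))
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    shuf <- base[perm, ]; shuf$order <- 1:3
    r2 <- aggregateScans(ScanSet("E1", "OD", shuf))
    for (p in recordCols) expect_identical(slot(r2, p), slot(r1, p))
  }
  # each aggregated parameter is one of the observed values (odd count)
  for (p in scanCols) expect_true(slot(r1, p) %in% base[[p]])
})

test_that("missing-in-all-scans propagates as NA and is caught by QC", {
  s <- ScanSet("E1", "OD", data.frame(order = 1:3, k1_D = 43, k2_D = 44,
    kmax_D = 45, cct_um = NA_real_, axial_length_mm = 24.1, acd_mm = 3.2))
  r <- aggregateScans(s)
  expect_true(is.na(r@cct_um))
  qc <- validateRecord(r)
  expect_equal(qc@status, "excluded")
  expect_true("incomplete" %in% qc@reasons)
})

test_that("QC passes the reference-mean record and flags implausible values", {
  expect_equal(validateRecord(referenceMeanRecord())@status, "pass")
  thin <- referenceMeanRecord(); thin@cct_um <- 100
  qc <- validateRecord(thin)
  expect_equal(qc@status, "excluded")
  expect_true("implausible_range" %in% qc@reasons)
  # inconsistent keratometry ordering
  bad <- BiometricRecord("E1", "OD", k1_D = 45, k2_D = 44, kmax_D = 46,
                         cct_um = 540, axial_length_mm = 24, acd_mm = 3.2,
                         astigmatism_D = 1)
  expect_true("inconsistent" %in% validateRecord(bad)@reasons)
  low <- referenceMeanRecord(); low@kmax_D <- low@k2_D - 1
  expect_true("inconsistent" %in% validateRecord(low)@reasons)
  # status/reasons invariant
  expect_length(validateRecord(referenceMeanRecord())@reasons, 0)
})

test_that("derived features match the reference cohort arithmetic", {
  r <- referenceMeanRecord()
  f <- deriveFeatures(r)
  # the published mean astigmatism equals the K2-K1 convention exactly
  expect_equal(f@astig_kdiff_D, 1.15, tolerance = 1e-12)
  expect_equal(f@mean_k_D, (43.21 + 44.36) / 2)
  f2 <- deriveFeatures(BiometricRecord("E1", "OD", k1_D = 43, k2_D = 45,
    kmax_D = 48, cct_um = 540, axial_length_mm = 24, acd_mm = 3.2))
  expect_equal(f2@kmax_excess_D, 4.0)
  sym <- deriveFeatures(BiometricRecord("E1", "OD", k1_D = 44, k2_D = 44,
    kmax_D = 44.5, cct_um = 540, axial_length_mm = 24, acd_mm = 3.2))
  expect_equal(sym@astig_kdiff_D, 0)
  expect_equal(sym@mean_k_D, 44.0)
  # determinism bit-for-bit
  expect_identical(deriveFeatures(r)@mean_k_D, f@mean_k_D)
  miss <- referenceMeanRecord(); miss@kmax_D <- NA_real_
  expect_error(deriveFeatures(miss), "missing")
})
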