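test_that("cohort sampling is seeded, reproducible and validates its spec", {
  spec <- cohortSpec(25, seed = 11)
  a <- sampleCohort(spec)
  b <- sampleCohort(spec)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  expect_identical(sampleCohort(cohortSpec(0, seed = 1)), list())
  expect_error(cohortSpec(-1, seed = 1), "non-negative")
  expect_error(cohortSpec(5, kcFraction = 1.5, seed = 1), "kcFraction")
  expect_error(cohortSpec(5), "seed")
  # no hidden global randomness: global RNG state untouched
  withr::with_seed(123, {
    before <- .Random.seed
    sampleCohort(spec)
    expect_identical(.Random.seed, before)
  })
})

test_that("labeled mode produces the steep-Kmax/thin-cornea class signature", {
  co <- sampleCohort(cohortSpec(400, mode = "labeled", kcFraction = 0.5,
                                seed = 3))
  lab <- vapply(co, function(e) e@label, character(1))
  expect_setequal(unique(lab), c("normal", "early_kc"))
  ex <- vapply(co, function(e) {
    f <- deriveFeatures(e@trueParams); f@kmax_excess_D
  }, numeric(1))
  cct <- vapply(co, function(e) e@trueParams@cct_um, numeric(1))
  expect_gt(mean(ex[lab == "early_kc"]), mean(ex[lab == "normal"]))
  expect_lt(mean(cct[lab == "early_kc"]), mean(cct[lab == "normal"]))
  # keratoconic eyes carry a cone, normals do not
  amp <- vapply(co, function(e) e@cone[["amplitude_D"]], numeric(1))
  expect_true(all(amp[lab == "early_kc"] > 0))
  expect_true(all(amp[lab == "normal"] == 0))
})

test_that("every labeled-mode eye passes QC through the scan pipeline", {
  co <- sampleCohort(cohortSpec(150, mode = "labeled", seed = 19))
  for (i in seq_along(co)) {
    s <- simulateRepeatScans(co[[i]], seed = deriveSeed(19, paste0("s", i)))
    expect_equal(validateRecord(aggregateScans(s))@status, "pass")
  }
})

test_that("zero scan noise reproduces the true parameters exactly", {
  eye <- fixedEye(label = "early_kc", astig = 1.2, excess = 4)
  zero <- setNames(rep(0, 6), scanCols)
  s <- simulateRepeatScans(eye, k = 3, noise = zero, seed = 4)
  for (p in scanCols)
    expect_equal(unique(s@scans[[p]]), slot(eye@trueParams, p))
  r <- aggregateScans(s)
  for (p in recordCols)
    expect_equal(slot(r, p), slot(eye@trueParams, p))
  expect_error(simulateRepeatScans(eye, noise = setNames(rep(-1, 6), scanCols),
                                   seed = 1), "non-negative")
  expect_error(simulateRepeatScans(eye, k = 0, seed = 1), ">= 1")
})

test_that("median-of-three beats a single scan in RMSE against truth", {
  co <- sampleCohort(cohortSpec(1000, mode = "labeled", seed = 31))
  errMed <- errOne <- numeric(length(co))
  for (i in seq_along(co)) {
    s <- simulateRepeatScans(co[[i]], seed = deriveSeed(31, paste0("n", i)))
    truth <- co[[i]]@trueParams@k1_D
    errMed[i] <- aggregateScans(s)@k1_D - truth
    errOne[i] <- s@scans$k1_D[1] - truth
  }
  expect_lt(sqrt(mean(errMed^2)), sqrt(mean(errOne^2)))
})

test_that("curvature-map rendering matches its closed form", {
  # degenerate case: no astigmatism, no cone -> constant disc at mean K
  flat <- renderCurvatureMap(fixedEye(k1 = 44), size = 64)
  v <- mapValues(flat)
  disc <- v != flat@background
  expect_true(all(abs(v[disc] - 44) < 1e-12))
  # disc mean of a cone-free bowtie map equals mean K within quadrature error
  bow <- renderCurvatureMap(fixedEye(k1 = 43, astig = 2), size = 64)
  bv <- mapValues(bow)
  expect_lt(abs(mean(bv[bv != bow@background]) - 44), 0.05)
  # inferior cone puts the global maximum in the inferior half-disc
  kc <- renderCurvatureMap(fixedEye(label = "early_kc", astig = 1, excess = 4,
                                    coneAngle = 270))
  idx <- computeMapIndices(kc)
  expect_gt(idx$max_angle_deg, 180)
  expect_lt(idx$max_angle_deg, 360)
  expect_error(renderCurvatureMap(fixedEye(), size = 0), "positive")
})

test_that("cone amplitude calibrates the map maximum near Kmax", {
  eye <- fixedEye(label = "early_kc", astig = 1.5, excess = 4.5)
  m <- renderCurvatureMap(eye)
  expect_equal(max(mapValues(m)), eye@trueParams@kmax_D, tolerance = 0.05)
})

test_that("cohort files round-trip and the manifest tracks content", {
  dir <- withr::local_tempdir()
  co <- sampleCohort(cohortSpec(4, seed = 13))
  ss <- lapply(seq_along(co), function(i)
    simulateRepeatScans(co[[i]], seed = deriveSeed(13, paste0("w", i))))
  maps <- lapply(co, renderCurvatureMap, size = 48)
  man <- writeCohort(co, ss, maps, dir)
  # n eyes -> n map files and one manifest
  expect_length(list.files(file.path(dir, "maps"), pattern = "\\.csv$"), 4)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  # parse_records round trip reproduces the scan sets
  back <- parseRecords(file.path(dir, "records.json"))
  expect_length(back, 4)
  for (i in seq_along(ss))
    expect_equal(back[[i]]@scans, ss[[i]]@scans, tolerance = 1e-12)
  # labels live in a separate file
  labs <- read.csv(file.path(dir, "labels.csv"))
  expect_setequal(labs$eye_id, vapply(co, eyeId, character(1)))
  # checksums change iff content changes
  dir2 <- withr::local_tempdir()
  man2 <- writeCohort(co, ss, maps, dir2)
  expect_identical(man$md5, man2$md5)
  co3 <- sampleCohort(cohortSpec(4, seed = 14))
  ss3 <- lapply(seq_along(co3), function(i)
    simulateRepeatScans(co3[[i]], seed = deriveSeed(14, paste0("w", i))))
  dir3 <- withr::local_tempdir()
  man3 <- writeCohort(co3, ss3, lapply(co3, renderCurvatureMap, size = 48), dir3)
  expect_false(identical(man$md5, man3$md5))
  # map CSV round trip
  m2 <- readCurvatureMapCSV(file.path(dir, "maps", paste0(eyeId(co[[1]]), ".csv")))
  expect_equal(mapValues(m2), mapValues(maps[[1]]), tolerance = 1e-12)
  expect_equal(m2@pixelSize_mm, maps[[1]]@pixelSize_mm)
})

test_that("marginal mode recovers the reference marginal statistics", {
  co <- sampleCohort(cohortSpec(4000, mode = "marginal", seed = 5))
  st <- referenceCohortStats()
  for (i in seq_len(nrow(st))) {
    v <- vapply(co, function(e) slot(e@trueParams, st$param[i]), numeric(1))
    se <- st$sd[i] / sqrt(length(v))
    expect_lt(abs(mean(v) - st$mean[i]), 4 * se)
    expect_equal(sd(v), st$sd[i], tolerance = 0.1)
  }
})
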