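# Heavier benchmark runs shared between module tests and the acceptance
# suite; computed lazily once per test session and cached.

if (!exists(".benchCache", inherits = FALSE)) .benchCache <- new.env()

# symbolic-only five-fold CV on the default labeled cohort (n = 1000, seed 7)
symbolicCVBenchmark <- function() {
  if (is.null(.benchCache$cv)) {
    spec <- cohortSpec(1000, mode = "labeled", kcFraction = 0.5, seed = 7)
    co <- sampleCohort(spec)
    recs <- lapply(seq_along(co), function(i)
      aggregateScans(simulateRepeatScans(
        co[[i]], seed = deriveSeed(7, paste0("scan-", i)))))
    labels <- stats::setNames(vapply(co, function(e) e@label, character(1)),
                              vapply(co, eyeId, character(1)))
    .benchCache$cv <- list(
      cohort = co, records = recs, labels = labels,
      result = suppressMessages(
        runCVExperiment(recs, labels, k = 5, seed = 7, nBoot = 200)))
  }
  .benchCache$cv
}

# 200 strongly separated synthetic maps, default compact encoder, 80/20 split
encoderBenchmark <- function() {
  if (is.null(.benchCache$enc)) {
    spec <- cohortSpec(200, mode = "labeled", kcFraction = 0.5, seed = 21)
    co <- sampleCohort(spec)
    maps <- lapply(co, renderCurvatureMap)
    labels <- vapply(co, function(e) e@label, character(1))
    heldOut <- withr::with_seed(99, unlist(lapply(
      split(seq_along(co), labels),
      function(ix) sample(ix, round(0.2 * length(ix))))))
    train <- setdiff(seq_along(co), heldOut)
    enc <- trainEncoder(maps[train], labels[train],
                        cfg = encoderConfig(seed = 77))
    scores <- vapply(maps[heldOut], neuralScore, numeric(1), enc = enc)
    .benchCache$enc <- list(
      encoder = enc, maps = maps, labels = labels, heldOut = heldOut,
      scores = scores, y = as.integer(labels[heldOut] == "early_kc"))
  }
  .benchCache$enc
}

# tiny encoder config for gradient checks and determinism tests
tinyEncoderConfig <- function(seed = 1) {
  encoderConfig(gridSize = 16, convChannels = c(3, 4), patch = 2, blocks = 1,
                heads = 2, dim = 8, mlpDim = 12, maxEpochs = 2, batchSize = 8,
                seed = seed)
}

tinyMapSet <- function(n = 16, seed = 5) {
  spec <- cohortSpec(n, mode = "labeled", kcFraction = 0.5, seed = seed)
  co <- sampleCohort(spec)
  list(maps = lapply(co, renderCurvatureMap, size = 16),
       labels = vapply(co, function(e) e@label, character(1)))
}
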