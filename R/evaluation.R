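#' @include AllClasses.R inference.R encoder.R
NULL

#' Build a (optionally stratified) k-fold plan
#'
#' Seeded shuffle followed by round-robin assignment; with labels supplied
#' the round-robin runs within each class with a carried counter, so folds
#' are stratified and overall fold sizes still differ by at most one.
#'
#' @param eyeIds character vector of unique eye identifiers.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @param labels optional labels parallel to \code{eyeIds} for
#'   stratification.
#' @return list: \code{k}, \code{assignments} (named integer fold index per
#'   eye), \code{seed}.
#' @export
makeFolds <- function(eyeIds, k, seed, labels = NULL) {
  n <- length(eyeIds)
  if (k < 2) stop("k must be >= 2")
  if (n < k) stop("cannot make ", k, " folds from ", n, " eyes")
  if (anyDuplicated(eyeIds)) stop("eyeIds must be unique")
  withSeed(seed, {
    assign <- integer(n)
    cursor <- 0L
    groups <- if (is.null(labels)) list(seq_len(n)) else
      split(seq_len(n), as.character(labels))
    for (ix in groups) {
      ix <- if (length(ix) > 1) sample(ix) else ix
      assign[ix] <- ((cursor + seq_along(ix) - 1L) %% k) + 1L
      cursor <- cursor + length(ix)
    }
    list(k = as.integer(k), assignments = stats::setNames(assign, eyeIds),
         seed = as.integer(seed))
  })
}

#' Confusion-matrix metrics for binary predictions
#'
#' Standard definitions with the positive class coded 1: sensitivity
#' TP/(TP+FN), specificity TN/(TN+FP), accuracy (TP+TN)/n, F1 =
#' 2PR/(P+R). A metric whose denominator is zero (for example sensitivity
#' with no positive labels) is returned as NaN with a warning, never as a
#' silent zero.
#'
#' @param labels binary labels (0/1, logical, or a 2-level factor with the
#'   positive level second).
#' @param predictions binary predictions, same coding.
#' @return list: tp, fp, tn, fn, sensitivity, specificity, accuracy,
#'   precision, f1.
#' @export
confusionMetrics <- function(labels, predictions) {
  if (!length(labels)) stop("empty input")
  if (length(labels) != length(predictions)) stop("length mismatch")
  y <- as01(labels); p <- as01(predictions)
  tp <- sum(y == 1 & p == 1); fp <- sum(y == 0 & p == 1)
  tn <- sum(y == 0 & p == 0); fn <- sum(y == 1 & p == 0)
  sdiv <- function(num, den, what) {
    if (den == 0) {
      warning(what, " is undefined (zero denominator); returning NaN",
              call. = FALSE)
      NaN
    } else num / den
  }
  sens <- sdiv(tp, tp + fn, "sensitivity")
  spec <- sdiv(tn, tn + fp, "specificity")
  prec <- sdiv(tp, tp + fp, "precision")
  f1 <- if (!is.nan(prec) && !is.nan(sens) && (prec + sens) > 0)
    2 * prec * sens / (prec + sens)
  else sdiv(0, 0, "F1")
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = sens, specificity = spec,
       accuracy = (tp + tn) / length(y), precision = prec, f1 = f1)
}

as01 <- function(x) {
  if (is.factor(x)) as.integer(x) - 1L
  else if (is.logical(x)) as.integer(x)
  else {
    u <- unique(x)
    if (!all(u %in% c(0, 1))) stop("labels/predictions must be binary (0/1)")
    as.integer(x)
  }
}

#' ROC curve, AUC and bootstrap confidence interval
#'
#' AUC is the Mann-Whitney rank statistic: the probability that a random
#' positive outscores a random negative, ties counted half. The curve is a
#' threshold sweep over the unique scores (predict positive when score >=
#' threshold), anchored at (0,0) and (1,1). The confidence interval is the
#' 2.5/97.5 percentile over a seeded case-resampling bootstrap of
#' (label, score) pairs; resamples that lose a class are redrawn.
#'
#' @param labels binary labels (positive = 1).
#' @param scores numeric scores, higher = more positive.
#' @param nBoot bootstrap replicates (0 disables the CI).
#' @param seed seed for the bootstrap.
#' @return list: \code{curve} (data.frame fpr, tpr, threshold), \code{auc},
#'   \code{auc_ci} (length-2, NA when nBoot = 0), \code{n_boot}.
#' @export
rocAuc <- function(labels, scores, nBoot = 1000, seed = 1) {
  y <- as01(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (length(y) != length(scores)) stop("length mismatch")
  auc <- aucRank(y, scores)
  thr <- sort(unique(scores), decreasing = TRUE)
  nPos <- sum(y == 1); nNeg <- sum(y == 0)
  tpr <- vapply(thr, function(t) sum(scores >= t & y == 1) / nPos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0) / nNeg, numeric(1))
  curve <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1),
                      threshold = c(Inf, thr, -Inf))
  ci <- c(NA_real_, NA_real_)
  if (nBoot > 0) {
    boots <- withSeed(seed, vapply(seq_len(nBoot), function(i) {
      repeat {
        ix <- sample.int(length(y), replace = TRUE)
        if (length(unique(y[ix])) == 2) break
      }
      aucRank(y[ix], scores[ix])
    }, numeric(1)))
    ci <- unname(stats::quantile(boots, c(0.025, 0.975), type = 7))
  }
  list(curve = curve, auc = auc, auc_ci = ci, n_boot = nBoot)
}

# midrank AUC (half credit for ties)
aucRank <- function(y, s) {
  r <- rank(s, ties.method = "average")
  nPos <- sum(y == 1); nNeg <- sum(y == 0)
  (sum(r[y == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Cohen's kappa for two raters
#'
#' \eqn{\kappa = (p_o - p_e) / (1 - p_e)} with expected agreement from the
#' marginal products. When both raters are constant and identical the
#' statistic is undefined (\eqn{p_e = 1}); NaN is returned with a warning.
#'
#' @param a,b equal-length rating vectors over a shared category space.
#' @return scalar kappa.
#' @export
cohensKappa <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  lev <- sort(unique(c(as.character(a), as.character(b))))
  ta <- table(factor(a, lev), factor(b, lev))
  n <- sum(ta)
  po <- sum(diag(ta)) / n
  pe <- sum(rowSums(ta) * colSums(ta)) / n^2
  if (pe >= 1) {
    warning("expected agreement is 1; kappa undefined, returning NaN",
            call. = FALSE)
    return(NaN)
  }
  (po - pe) / (1 - pe)
}

#' Youden-optimal threshold of a score
#'
#' @param labels binary labels.
#' @param scores numeric scores.
#' @return the score threshold maximizing sensitivity + specificity - 1.
#' @export
youdenThreshold <- function(labels, scores) {
  y <- as01(labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  j <- vapply(thr, function(t) {
    p <- as.integer(scores >= t)
    sum(p & y) / sum(y) + sum(!p & !y) / sum(!y) - 1
  }, numeric(1))
  thr[which.max(j)]
}

#' Cross-validated end-to-end evaluation of the screening pipeline
#'
#' Runs stratified k-fold cross-validation of the inference pipeline on a
#' labeled cohort. In symbolic-only mode (no encoder configuration) each
#' held-out eye is scored by the noisy-OR posterior alone and the run is
#' fully deterministic given the seed. With an encoder configuration and
#' maps, a fresh encoder is trained per fold on the training folds only and
#' the held-out scores are the fused posterior. The scoring path receives
#' records (and maps) only; held-out labels are touched exclusively when
#' the scores are evaluated afterwards, and any overlap between a fold's
#' train and test eyes is a hard error.
#'
#' Confusion metrics are reported at the configured decision threshold and
#' at the pooled Youden-optimal threshold, per fold and pooled (pooled is
#' primary). Results, fold plan, configuration snapshot and a log are
#' written to \code{outDir} when given.
#'
#' @param records list of QC-passing [BiometricRecord-class].
#' @param labels named or parallel character labels ("normal"/"early_kc").
#' @param g a [KnowledgeGraph-class].
#' @param cfg an [inferenceConfig()].
#' @param maps optional named list of [CurvatureMap-class] per eye.
#' @param encCfg optional [encoderConfig()]; requires \code{maps}.
#' @param k fold count.
#' @param seed run seed (folds, per-fold encoder seeds, bootstrap).
#' @param outDir optional results directory.
#' @param nBoot bootstrap replicates for the pooled AUC CI.
#' @return list: \code{scores} (data.frame eye_id, fold, label, score),
#'   \code{pooled} (metrics at tau_d and Youden, ROC, AUC + CI),
#'   \code{perFold} (list of per-fold metric sets), \code{folds}.
#' @export
runCVExperiment <- function(records, labels, g = buildDefaultGraph(),
                            cfg = inferenceConfig(), maps = NULL,
                            encCfg = NULL, k = 5, seed, outDir = NULL,
                            nBoot = 1000) {
  ids <- vapply(records, eyeId, character(1))
  names(records) <- ids
  if (is.null(names(labels))) names(labels) <- ids
  labels <- labels[ids]
  if (anyNA(labels)) stop("every record needs a label")
  if (!is.null(encCfg) && is.null(maps))
    stop("encoder-based evaluation requires curvature maps")
  folds <- makeFolds(ids, k, deriveSeed(seed, "folds"), labels = labels)
  rows <- list()
  perFold <- vector("list", k)
  for (fold in seq_len(k)) {
    testIds <- ids[folds$assignments[ids] == fold]
    trainIds <- setdiff(ids, testIds)
    if (length(intersect(trainIds, testIds)))
      stop("leakage: eye(s) in both train and test of fold ", fold)
    enc <- NULL
    if (!is.null(encCfg)) {
      ec <- encCfg
      ec$seed <- deriveSeed(seed, paste0("encoder-fold-", fold))
      enc <- trainEncoder(maps[trainIds], labels[trainIds], g, ec)
    }
    sc <- vapply(testIds, function(id) {
      tr <- inferEye(records[[id]], g, cfg,
                     map = if (!is.null(maps)) maps[[id]] else NULL,
                     encoder = enc)
      tr@posterior$p_kc
    }, numeric(1))
    rows[[fold]] <- data.frame(eye_id = testIds, fold = fold,
                               label = unname(labels[testIds]),
                               score = unname(sc), stringsAsFactors = FALSE)
  }
  scores <- do.call(rbind, rows)
  y <- as.integer(scores$label == "early_kc")
  roc <- rocAuc(y, scores$score, nBoot = nBoot,
                seed = deriveSeed(seed, "bootstrap"))
  yth <- youdenThreshold(y, scores$score)
  pooled <- list(
    at_tau_d = confusionMetrics(y, as.integer(scores$score >= cfg$tauD)),
    at_youden = confusionMetrics(y, as.integer(scores$score >= yth)),
    youden_threshold = yth, tau_d = cfg$tauD,
    auc = roc$auc, auc_ci = roc$auc_ci)
  for (fold in seq_len(k)) {
    sf <- scores[scores$fold == fold, ]
    yf <- as.integer(sf$label == "early_kc")
    perFold[[fold]] <- list(
      fold = fold, n = nrow(sf),
      at_tau_d = confusionMetrics(yf, as.integer(sf$score >= cfg$tauD)),
      auc = if (length(unique(yf)) == 2)
        rocAuc(yf, sf$score, nBoot = 0)$auc else NA_real_)
  }
  res <- list(scores = scores, pooled = pooled, perFold = perFold,
              folds = folds, roc = roc$curve)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeJSONCanonical(list(pooled = pooled, per_fold = perFold),
                       file.path(outDir, "metrics.json"))
    utils::write.csv(roc$curve, file.path(outDir, "roc_points.csv"),
                     row.names = FALSE)
    writeJSONCanonical(list(k = folds$k, seed = folds$seed,
                            assignments = as.list(folds$assignments)),
                       file.path(outDir, "folds.json"))
    writeJSONCanonical(list(inference = cfg, encoder = encCfg, k = k,
                            seed = seed, n_boot = nBoot,
                            mode = if (is.null(encCfg)) "symbolic" else "fused"),
                       file.path(outDir, "config_snapshot.json"))
    writeLines(sprintf("run seed=%d k=%d n=%d mode=%s pooled_auc=%.6f",
                       seed, k, length(ids),
                       if (is.null(encCfg)) "symbolic" else "fused",
                       roc$auc),
               file.path(outDir, "log.txt"))
  }
  res
}
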