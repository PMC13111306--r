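# Shared fixture builders and independent oracles for the test suite.

scanCols <- c("k1_D", "k2_D", "kmax_D", "cct_um", "axial_length_mm", "acd_mm")
recordCols <- c(scanCols, "astigmatism_D")

# a record at the reference-cohort mean values (passes QC by construction)
referenceMeanRecord <- function(eyeId = "REF001") {
  BiometricRecord(eyeId, "OD", k1_D = 43.21, k2_D = 44.36, kmax_D = 46.02,
                  cct_um = 532.6, axial_length_mm = 24.18, acd_mm = 3.21,
                  astigmatism_D = 1.15)
}

# write a two-eye JSON fixture in the documented schema
writeTwoEyeJSON <- function(path) {
  rec <- function(id, lat, base) list(
    eye_id = id, laterality = lat, site = "unit-test",
    scans = lapply(1:3, function(o) list(
      order = o, k1_D = base + 0.1 * o, k2_D = base + 1 + 0.1 * o,
      kmax_D = base + 2, cct_um = 540 - o, axial_length_mm = 24.1,
      acd_mm = 3.2)))
  jsonlite::write_json(list(rec("E1", "OD", 43), rec("E2", "OS", 44)),
                       path, auto_unbox = TRUE, digits = NA)
  path
}

# minimal graph with k arbitrary-weight rules into the KC diagnosis node;
# used to drive inferPosterior against the enumeration oracle
ruleOnlyGraph <- function(weights, prior = 0.05) {
  k <- length(weights)
  nodes <- data.frame(
    node_id = c(paste0("P", seq_len(k)), "early_keratoconus", "normal_cornea"),
    category = c(rep("parameter", k), "diagnosis", "diagnosis"),
    label = NA_character_, label_en = NA_character_, label_zh = NA_character_,
    stringsAsFactors = FALSE)
  edges <- data.frame(
    source = paste0("P", seq_len(k)), target = "early_keratoconus",
    weight = weights, rule_id = paste0("T", seq_len(k)), feature = "kmax_D",
    direction = "above", threshold = 47, softness = 1,
    stringsAsFactors = FALSE)
  KnowledgeGraph(nodes, edges,
                 priors = c(early_keratoconus = prior,
                            normal_cornea = 1 - prior))
}

# synthetic evidence table matching ruleOnlyGraph
evidenceFor <- function(activations, weights, eyeId = "E1") {
  k <- length(activations)
  e <- data.frame(rule_id = paste0("T", seq_len(k)), feature = "kmax_D",
                  value = 48, direction = "above", threshold = 47,
                  softness = 1, activation = activations, weight = weights,
                  source = paste0("P", seq_len(k)),
                  target = "early_keratoconus", stringsAsFactors = FALSE)
  attr(e, "eyeId") <- eyeId
  e
}

# ORACLE: brute-force enumeration of the noisy-OR causal model — sum over
# all 2^k cause-activation outcomes, each cause i active with probability
# a_i and, when active, producing the effect with probability w_i; the leak
# (prior) can produce the effect on its own.
noisyORByEnumeration <- function(p0, weights, activations) {
  k <- length(weights)
  total <- 0
  for (mask in 0:(2^k - 1)) {
    active <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1)))
    pOutcome <- prod(ifelse(active, activations, 1 - activations))
    pEffect <- 1 - (1 - p0) * prod(1 - weights[active])
    total <- total + pOutcome * pEffect
  }
  total
}

# ORACLE: AUC by exhaustive enumeration of positive-negative pairs with
# half credit for ties.
aucByPairEnumeration <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# fully deterministic mean-level eye for map tests
fixedEye <- function(label = "normal", k1 = 43, astig = 0, excess = 0,
                     coneAngle = 270, coneR = 1.5, coneSigma = 1.0,
                     cct = 545) {
  k2 <- k1 + astig
  meanK <- (k1 + k2) / 2
  kmax <- max(meanK + excess, k2)
  rec <- BiometricRecord("FIX1", "OD", k1_D = k1, k2_D = k2, kmax_D = kmax,
                         cct_um = cct, axial_length_mm = 24.2, acd_mm = 3.2)
  amp <- if (label == "early_kc")
    max(kmax - meanK - (astig / 2) * cos(2 * (coneAngle - 90) * pi / 180), 0.1)
  else 0
  new("SyntheticEye", eyeId = "FIX1", label = label, trueParams = rec,
      cone = c(amplitude_D = amp, center_radius_mm = coneR,
               center_angle_deg = coneAngle, sigma_mm = coneSigma))
}
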