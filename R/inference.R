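#' @include AllClasses.R knowledge-graph.R
NULL

#' Inference configuration
#'
#' @param prior prior probability of early keratoconus in (0,1); the noisy-OR
#'   leak term. Default 0.05, a screening-population prior.
#' @param alpha neural/symbolic fusion weight in [0,1]; 0 (symbolic-only) is
#'   the out-of-box mode, so the system is fully functional without a
#'   trained encoder. Default fused weight when an encoder is supplied: 0.30.
#' @param tauD decision threshold on the posterior in (0,1); default 0.30
#'   (screening favors sensitivity).
#' @param clamp probability clamp applied before logit transforms.
#' @return a validated configuration list.
#' @export
inferenceConfig <- function(prior = 0.05, alpha = 0.30, tauD = 0.30,
                            clamp = 1e-6) {
  if (!num1(prior) || prior <= 0 || prior >= 1) stop("prior must be in (0,1)")
  if (!num1(alpha) || alpha < 0 || alpha > 1) stop("alpha must be in [0,1]")
  if (!num1(tauD) || tauD <= 0 || tauD >= 1) stop("tauD must be in (0,1)")
  list(prior = prior, alpha = alpha, tauD = tauD, clamp = clamp)
}

#' Noisy-OR posterior for early keratoconus
#'
#' Combines the activated rules pointing into the early-keratoconus
#' diagnosis node under the noisy-OR causal model with the prior as leak:
#' \deqn{p_{KC} = 1 - (1 - p_0) \prod_i (1 - w_i a_i)}
#' where \eqn{w_i} is the edge weight (link probability) and \eqn{a_i} the
#' rule activation. Each rule's contribution is reported as \eqn{w_i a_i}.
#' With no active rules the posterior equals the prior. The normal-cornea
#' diagnosis is the complement, \eqn{1 - p_{KC}}.
#'
#' @param e evidence activation from [activateEvidence()].
#' @param g the [KnowledgeGraph-class] the evidence was computed on.
#' @param cfg an [inferenceConfig()].
#' @return a [DiagnosisResult-class].
#' @export
inferPosterior <- function(e, g, cfg = inferenceConfig()) {
  known <- g@edges$rule_id[!is.na(g@edges$rule_id)]
  bad <- setdiff(e$rule_id, known)
  if (length(bad))
    stop("evidence references rule(s) absent from the graph: ",
         paste(bad, collapse = ", "))
  rows <- e[e$target == "early_keratoconus", , drop = FALSE]
  p0 <- cfg$prior
  contrib <- rows$weight * rows$activation
  pkc <- 1 - (1 - p0) * prod(1 - contrib)
  cdf <- data.frame(rule_id = rows$rule_id, feature = rows$feature,
                    weight = rows$weight, activation = rows$activation,
                    contribution = contrib, stringsAsFactors = FALSE)
  cdf <- cdf[order(-cdf$contribution), , drop = FALSE]
  rownames(cdf) <- NULL
  res <- new("DiagnosisResult", pKC = pkc, pSource = "symbolic",
             contributions = cdf, eyeId = attr(e, "eyeId") %||% NA_character_)
  attr(res, "prior") <- p0
  res
}

#' Fuse symbolic and neural probabilities
#'
#' Logit-linear opinion pool: \eqn{\mathrm{logit}(p) = (1-\alpha)\,
#' \mathrm{logit}(p_{sym}) + \alpha\, \mathrm{logit}(p_{neur})}. Both inputs
#' are clamped to \code{[clamp, 1-clamp]} first. \eqn{\alpha = 0} returns
#' the symbolic probability unchanged; \eqn{\alpha = 1} the neural one.
#'
#' @param pSym symbolic posterior in (0,1).
#' @param pNeur neural score in (0,1).
#' @param alpha fusion weight in [0,1].
#' @param clamp probability clamp before the logit.
#' @return fused probability.
#' @export
fuseScores <- function(pSym, pNeur, alpha, clamp = 1e-6) {
  if (!num1(alpha) || alpha < 0 || alpha > 1) stop("alpha must be in [0,1]")
  ps <- clampProb(pSym, clamp); pn <- clampProb(pNeur, clamp)
  stats::plogis((1 - alpha) * logit(ps) + alpha * logit(pn))
}

#' Decide refractive-surgery eligibility
#'
#' Contraindicated iff the keratoconus posterior reaches the decision
#' threshold \eqn{\tau_d} OR any hard (softness 0) parameter-to-decision
#' rule targeting the contraindication node fired with activation 1;
#' otherwise candidate. All triggers are listed in the result.
#'
#' @param d a [DiagnosisResult-class].
#' @param e the evidence activation used for \code{d}.
#' @param g the [KnowledgeGraph-class].
#' @param cfg an [inferenceConfig()].
#' @return a [DecisionResult-class].
#' @export
decideEligibility <- function(d, e, g, cfg = inferenceConfig()) {
  hard <- e[e$target == "surgery_contraindicated" & e$softness == 0 &
              e$activation == 1, , drop = FALSE]
  posterior_hit <- d@pKC >= cfg$tauD
  trig <- hard[, c("rule_id", "feature", "value", "threshold", "direction"),
               drop = FALSE]
  rownames(trig) <- NULL
  elig <- if (posterior_hit || nrow(trig)) "contraindicated" else "candidate"
  new("DecisionResult", eligibility = elig, triggers = trig, tauD = cfg$tauD,
      eyeId = d@eyeId)
}

#' Assemble the machine-readable reasoning trace
#'
#' Builds the ordered four-stage chain — measured parameters, rule
#' evaluations, posterior computation, decision rationale — from the
#' intermediate results of one eye's inference. Values are carried exactly
#' (no re-rounding); the trace posterior equals the diagnosis posterior
#' bit-for-bit. All stages must come from the same eye.
#'
#' @param r the [BiometricRecord-class].
#' @param f its [DerivedFeatures-class].
#' @param e the evidence activation.
#' @param d the [DiagnosisResult-class].
#' @param dec the [DecisionResult-class].
#' @return a [ReasoningTrace-class].
#' @export
buildTrace <- function(r, f, e, d, dec) {
  ids <- c(r@eyeId, attr(e, "eyeId") %||% r@eyeId, d@eyeId, dec@eyeId)
  ids <- ids[!is.na(ids)]
  if (length(unique(ids)) != 1L)
    stop("stage mismatch: inputs come from different eyes (",
         paste(unique(ids), collapse = ", "), ")")
  params <- as.list(vapply(recordParamCols(), function(p) slot(r, p), numeric(1)))
  params$mean_k_D <- f@mean_k_D
  params$astig_kdiff_D <- f@astig_kdiff_D
  params$kmax_excess_D <- f@kmax_excess_D
  rules <- e
  rules$fired <- rules$activation >= 0.5
  attr(rules, "eyeId") <- NULL
  new("ReasoningTrace", eyeId = r@eyeId, parameters = params, rules = rules,
      posterior = list(prior = graphPriorOf(d), terms = d@contributions,
                       p_kc = d@pKC, source = d@pSource),
      decision = list(eligibility = dec@eligibility, triggers = dec@triggers,
                      tau_d = dec@tauD))
}

# the prior actually used lives in the config; recover it from the noisy-OR
# identity when no rule contributed, else carry it via attribute
graphPriorOf <- function(d) {
  pr <- attr(d, "prior")
  if (!is.null(pr)) return(pr)
  prod1 <- prod(1 - d@contributions$contribution)
  if (prod1 > 0) 1 - (1 - d@pKC) / prod1 else NA_real_
}

#' Run symbolic inference end-to-end for one record
#'
#' Convenience wrapper: derives features, activates evidence, computes the
#' noisy-OR posterior (optionally fused with a neural map score), decides
#' eligibility and assembles the trace.
#'
#' @param r a QC-passing [BiometricRecord-class].
#' @param g a [KnowledgeGraph-class].
#' @param cfg an [inferenceConfig()].
#' @param map optional [CurvatureMap-class] for the I-S asymmetry rule.
#' @param encoder optional [TrainedEncoder-class]; when present the map is
#'   scored neurally and fused at \code{cfg$alpha}.
#' @return a [ReasoningTrace-class].
#' @export
inferEye <- function(r, g, cfg = inferenceConfig(), map = NULL,
                     encoder = NULL) {
  f <- deriveFeatures(r)
  m <- if (!is.null(map)) computeMapIndices(map) else NULL
  e <- activateEvidence(r, f, m, g)
  d <- inferPosterior(e, g, cfg)
  if (!is.null(encoder) && !is.null(map) && cfg$alpha > 0) {
    pn <- neuralScore(map, encoder)
    d@pKC <- fuseScores(d@pKC, pn, cfg$alpha, cfg$clamp)
    d@pSource <- "fused"
  }
  dec <- decideEligibility(d, e, g, cfg)
  buildTrace(r, f, e, d, dec)
}

#' Serialize / deserialize a reasoning trace as JSON
#'
#' Lossless, versioned JSON round-trip of the full trace; numbers are
#' written at full double precision.
#'
#' @param t a [ReasoningTrace-class].
#' @param path optional file path; when NULL the JSON string is returned.
#' @return \code{traceToJSON}: a JSON string (or path invisibly);
#'   \code{traceFromJSON}: a [ReasoningTrace-class].
#' @export
traceToJSON <- function(t, path = NULL) {
  obj <- list(version = t@version, eye_id = t@eyeId,
              parameters = t@parameters,
              rules = t@rules,
              posterior = list(prior = t@posterior$prior,
                               terms = t@posterior$terms,
                               p_kc = t@posterior$p_kc,
                               source = t@posterior$source),
              decision = t@decision)
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17),
                          dataframe = "rows", na = "null")
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname traceToJSON
#' @param json a JSON string or file path.
#' @export
traceFromJSON <- function(json) {
  src <- if (file.exists(json[1]) && !grepl("^\\s*\\{", json[1])) json else json
  obj <- jsonlite::fromJSON(src, simplifyVector = TRUE)
  rules <- as.data.frame(obj$rules)
  terms <- as.data.frame(obj$posterior$terms)
  trig <- as.data.frame(obj$decision$triggers)
  new("ReasoningTrace", eyeId = obj$eye_id, parameters = obj$parameters,
      rules = rules,
      posterior = list(prior = obj$posterior$prior, terms = terms,
                       p_kc = obj$posterior$p_kc,
                       source = obj$posterior$source),
      decision = list(eligibility = obj$decision$eligibility,
                      triggers = trig, tau_d = obj$decision$tau_d),
      version = obj$version)
}
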