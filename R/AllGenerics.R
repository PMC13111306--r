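#' @include AllClasses.R
NULL

#' Accessors for CornealKG objects
#'
#' \code{eyeId} returns the eye identifier of an object; \code{mapValues}
#' the power grid of a curvature map; \code{graphNodes}/\code{graphEdges}/
#' \code{graphPriors} the components of a knowledge graph; \code{pKC} the
#' keratoconus posterior; \code{traceStages} the ordered stage list of a
#' reasoning trace; \code{reportSections} the rendered sections of a report.
#'
#' @param object a CornealKG S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("eyeId", function(object) standardGeneric("eyeId"))
#' @rdname accessors
#' @export
setGeneric("mapValues", function(object) standardGeneric("mapValues"))
#' @rdname accessors
#' @export
setGeneric("graphNodes", function(object) standardGeneric("graphNodes"))
#' @rdname accessors
#' @export
setGeneric("graphEdges", function(object) standardGeneric("graphEdges"))
#' @rdname accessors
#' @export
setGeneric("graphPriors", function(object) standardGeneric("graphPriors"))
#' @rdname accessors
#' @export
setGeneric("pKC", function(object) standardGeneric("pKC"))
#' @rdname accessors
#' @export
setGeneric("traceStages", function(object) standardGeneric("traceStages"))
#' @rdname accessors
#' @export
setGeneric("reportSections", function(object) standardGeneric("reportSections"))

#' @rdname accessors
#' @export
setMethod("eyeId", "ScanSet", function(object) object@eyeId)
#' @rdname accessors
#' @export
setMethod("eyeId", "BiometricRecord", function(object) object@eyeId)
#' @rdname accessors
#' @export
setMethod("eyeId", "SyntheticEye", function(object) object@eyeId)
#' @rdname accessors
#' @export
setMethod("eyeId", "CurvatureMap", function(object) object@eyeId)
#' @rdname accessors
#' @export
setMethod("eyeId", "ReasoningTrace", function(object) object@eyeId)
#' @rdname accessors
#' @export
setMethod("mapValues", "CurvatureMap", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("graphNodes", "KnowledgeGraph", function(object) object@nodes)
#' @rdname accessors
#' @export
setMethod("graphEdges", "KnowledgeGraph", function(object) object@edges)
#' @rdname accessors
#' @export
setMethod("graphPriors", "KnowledgeGraph", function(object) object@priors)
#' @rdname accessors
#' @export
setMethod("pKC", "DiagnosisResult", function(object) object@pKC)
#' @rdname accessors
#' @export
setMethod("pKC", "ReasoningTrace", function(object) object@posterior$p_kc)
#' @rdname accessors
#' @export
setMethod("traceStages", "ReasoningTrace", function(object) {
  list(parameters = object@parameters, rules = object@rules,
       posterior = object@posterior, decision = object@decision)
})
#' @rdname accessors
#' @export
setMethod("reportSections", "ClinicalReport", function(object) object@sections)

setMethod("show", "ScanSet", function(object) {
  cat(sprintf("ScanSet for eye %s (%s): %d scan(s)\n",
              object@eyeId, object@laterality, nrow(object@scans)))
})

setMethod("show", "BiometricRecord", function(object) {
  cat(sprintf("BiometricRecord %s (%s)\n", object@eyeId, object@laterality))
  v <- vapply(recordParamCols(), function(p) slot(object, p), numeric(1))
  print(round(v, 3))
})

setMethod("show", "QCResult", function(object) {
  cat(sprintf("QCResult: %s", object@status))
  if (length(object@reasons))
    cat(" [", paste(object@reasons, collapse = ", "), "]", sep = "")
  cat("\n")
  if (length(object@detail)) cat(paste0("  - ", object@detail, collapse = "\n"), "\n")
})

setMethod("show", "CurvatureMap", function(object) {
  n <- nrow(object@values)
  cat(sprintf("CurvatureMap %s: %dx%d grid, %.2f mm/px (extent %.1f mm), range %.2f-%.2f D\n",
              if (nzchar(object@eyeId)) object@eyeId else "<detached>",
              n, n, object@pixelSize_mm, n * object@pixelSize_mm,
              min(object@values), max(object@values)))
})

setMethod("show", "KnowledgeGraph", function(object) {
  tab <- table(object@nodes$category)
  cat(sprintf("KnowledgeGraph v%s: %d nodes (%s), %d edges, %d rule(s)\n",
              object@version, nrow(object@nodes),
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", "),
              nrow(object@edges), sum(!is.na(object@edges$rule_id))))
})

setMethod("show", "DiagnosisResult", function(object) {
  cat(sprintf("DiagnosisResult %s: P(early keratoconus) = %.4f (%s)\n",
              object@eyeId, object@pKC, object@pSource))
})

setMethod("show", "DecisionResult", function(object) {
  cat(sprintf("DecisionResult %s: %s (tau_d = %.2f, %d hard trigger(s))\n",
              object@eyeId, object@eligibility, object@tauD, nrow(object@triggers)))
})

setMethod("show", "ReasoningTrace", function(object) {
  cat(sprintf("ReasoningTrace %s: %d parameter(s), %d rule(s) (%d fired), p_kc = %.4f, %s\n",
              object@eyeId, length(object@parameters), nrow(object@rules),
              sum(object@rules$fired), object@posterior$p_kc,
              object@decision$eligibility))
})

setMethod("show", "TrainedEncoder", function(object) {
  cat(sprintf("TrainedEncoder: dim %d, %d epoch(s), best val loss %.4f\n",
              object@config$dim, nrow(object@history), min(object@history$val_loss)))
})

setMethod("show", "ClinicalReport", function(object) {
  cat(sprintf("ClinicalReport (%s, %s) for eye %s: %d sections\n",
              object@audience, object@language, object@eyeId,
              length(object@sections)))
})

setMethod("show", "SyntheticEye", function(object) {
  cat(sprintf("SyntheticEye %s [%s]: Kmax %.2f D, CCT %.0f um, cone amplitude %.2f D\n",
              object@eyeId, object@label, object@trueParams@kmax_D,
              object@trueParams@cct_um, object@cone[["amplitude_D"]]))
})
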