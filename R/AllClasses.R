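#' @import methods
NULL

#' ScanSet: raw repeated biometry scans for one eye
#'
#' Holds the k (default 3) consecutive raw measurement tuples acquired for a
#' single eye in one examination session, before median aggregation. The
#' \code{scans} slot is a data.frame with one row per scan and columns
#' \code{order, k1_D, k2_D, kmax_D, cct_um, axial_length_mm, acd_mm};
#' missing measurements are \code{NA}, never zero.
#'
#' Validity enforces structural constraints only (column presence, positive
#' values where present, unique acquisition order); clinical plausibility is
#' the job of [validateRecord()].
#'
#' @slot eyeId opaque eye identifier.
#' @slot laterality \code{"OD"}, \code{"OS"}, or \code{NA}.
#' @slot scans data.frame of raw scans (see above).
#' @slot metadata list of unknown input fields, preserved opaquely.
#' @export
setClass("ScanSet",
  representation(eyeId = "character", laterality = "character",
                 scans = "data.frame", metadata = "list"),
  prototype(metadata = list()))

setValidity("ScanSet", function(object) {
  msgs <- character()
  if (length(object@eyeId) != 1L || is.na(object@eyeId) || !nzchar(object@eyeId))
    msgs <- c(msgs, "eyeId must be a single non-empty string")
  if (length(object@laterality) != 1L ||
      !(is.na(object@laterality) || object@laterality %in% c("OD", "OS")))
    msgs <- c(msgs, "laterality must be 'OD', 'OS' or NA")
  need <- c("order", scanParamCols())
  miss <- setdiff(need, names(object@scans))
  if (length(miss))
    msgs <- c(msgs, paste0("scans is missing columns: ", paste(miss, collapse = ", ")))
  else {
    if (nrow(object@scans) < 1L) msgs <- c(msgs, "at least one scan is required")
    if (anyDuplicated(object@scans$order))
      msgs <- c(msgs, "duplicate acquisition order")
    vals <- as.matrix(object@scans[, scanParamCols()])
    if (any(vals <= 0, na.rm = TRUE))
      msgs <- c(msgs, "measurement values must be strictly positive when present")
  }
  if (length(msgs)) msgs else TRUE
})

#' BiometricRecord: aggregated per-eye biometry
#'
#' One eye's seven aggregated biometric parameters: flat and steep
#' keratometry (K1, K2, diopters), maximum keratometry (Kmax, diopters),
#' central corneal thickness (micrometers), axial length and anterior chamber
#' depth (millimeters) and corneal astigmatism magnitude (diopters).
#'
#' Validity is structural (scalar numeric slots, positive where present).
#' Clinical consistency (K2 >= K1, Kmax >= K2 - 0.5 D, astigmatism >= 0) is
#' checked by [validateRecord()], which must be able to inspect and flag
#' inconsistent records rather than have their construction fail.
#'
#' @slot eyeId,laterality as in [ScanSet-class].
#' @slot k1_D,k2_D,kmax_D keratometry in diopters.
#' @slot cct_um central corneal thickness in micrometers.
#' @slot axial_length_mm,acd_mm axial length / anterior chamber depth in mm.
#' @slot astigmatism_D corneal astigmatism magnitude (K2 - K1), diopters.
#' @export
setClass("BiometricRecord",
  representation(eyeId = "character", laterality = "character",
    k1_D = "numeric", k2_D = "numeric", kmax_D = "numeric",
    cct_um = "numeric", axial_length_mm = "numeric", acd_mm = "numeric",
    astigmatism_D = "numeric"))

setValidity("BiometricRecord", function(object) {
  msgs <- character()
  for (sl in recordParamCols()) {
    v <- slot(object, sl)
    if (length(v) != 1L) msgs <- c(msgs, paste0(sl, " must be a scalar"))
    else if (!is.na(v) && sl != "astigmatism_D" && v <= 0)
      msgs <- c(msgs, paste0(sl, " must be positive when present"))
  }
  if (length(msgs)) msgs else TRUE
})

#' QCResult: outcome of record-level quality control
#'
#' @slot status \code{"pass"} or \code{"excluded"}.
#' @slot reasons codes among \code{incomplete}, \code{implausible_range},
#'   \code{inconsistent}; non-empty iff status is \code{"excluded"}.
#' @slot detail human-readable detail strings, parallel to \code{reasons}.
#' @export
setClass("QCResult",
  representation(status = "character", reasons = "character", detail = "character"))

setValidity("QCResult", function(object) {
  ok <- (object@status == "excluded") == (length(object@reasons) > 0L)
  if (!ok) "status must be 'excluded' iff reasons is non-empty" else TRUE
})

#' DerivedFeatures: rule-facing features computed from a record
#'
#' @slot mean_k_D mean keratometry (K1+K2)/2, diopters.
#' @slot astig_kdiff_D keratometric astigmatism K2-K1, diopters.
#' @slot kmax_excess_D Kmax minus mean keratometry, diopters.
#' @export
setClass("DerivedFeatures",
  representation(mean_k_D = "numeric", astig_kdiff_D = "numeric",
                 kmax_excess_D = "numeric"))

#' SyntheticEye: latent ground-truth eye used by the simulator
#'
#' @slot eyeId identifier.
#' @slot label \code{"normal"}, \code{"early_kc"} or \code{"unlabeled"}.
#' @slot trueParams noise-free [BiometricRecord-class].
#' @slot cone latent cone descriptor: named numeric
#'   \code{(amplitude_D, center_radius_mm, center_angle_deg, sigma_mm)};
#'   amplitude 0 for non-ectatic eyes.
#' @export
setClass("SyntheticEye",
  representation(eyeId = "character", label = "character",
                 trueParams = "BiometricRecord", cone = "numeric"))

setValidity("SyntheticEye", function(object) {
  msgs <- character()
  if (!object@label %in% c("normal", "early_kc", "unlabeled"))
    msgs <- c(msgs, "label must be normal, early_kc or unlabeled")
  need <- c("amplitude_D", "center_radius_mm", "center_angle_deg", "sigma_mm")
  if (!all(need %in% names(object@cone)))
    msgs <- c(msgs, "cone must carry amplitude_D, center_radius_mm, center_angle_deg, sigma_mm")
  else if (object@label == "early_kc" && !(object@cone[["amplitude_D"]] > 0))
    msgs <- c(msgs, "early_kc eyes must have cone amplitude > 0")
  if (length(msgs)) msgs else TRUE
})

#' CurvatureMap: 2-D axial corneal power grid
#'
#' A square grid of axial corneal power in diopters on a physical millimeter
#' frame centered on the grid midpoint. Orientation: +y is superior and +x is
#' temporal-for-OD; matrix row 1 is the superior edge. Pixels outside the
#' corneal disc (radius = extent/2) carry the constant \code{background}
#' value so all entries stay finite.
#'
#' @slot values square numeric matrix, diopters.
#' @slot pixelSize_mm physical edge length of one pixel.
#' @slot background background power value outside the corneal disc.
#' @slot eyeId identifier of the eye the map belongs to ("" if detached).
#' @export
setClass("CurvatureMap",
  representation(values = "matrix", pixelSize_mm = "numeric",
                 background = "numeric", eyeId = "character"),
  prototype(eyeId = ""))

setValidity("CurvatureMap", function(object) {
  msgs <- character()
  if (nrow(object@values) != ncol(object@values)) msgs <- c(msgs, "grid must be square")
  if (!all(is.finite(object@values))) msgs <- c(msgs, "all map values must be finite")
  if (!num1(object@pixelSize_mm) || object@pixelSize_mm <= 0)
    msgs <- c(msgs, "pixelSize_mm must be a positive scalar")
  if (length(msgs)) msgs else TRUE
})

#' KnowledgeGraph: layered symbolic corneal knowledge graph
#'
#' A directed, layered graph over three node categories — biometric
#' \code{parameter} nodes, clinical \code{diagnosis} nodes and surgical
#' \code{decision} nodes. Edges may only point parameter->diagnosis,
#' diagnosis->decision or parameter->decision; parameter-source edges carry a
#' threshold rule (feature, direction, threshold, logistic softness) and a
#' weight in [0,1] giving the link probability used by noisy-OR inference.
#'
#' @slot nodes data.frame: node_id, category, label, label_en, label_zh.
#' @slot edges data.frame: source, target, weight, rule_id, feature,
#'   direction, threshold, softness (rule fields NA on diagnosis->decision
#'   edges).
#' @slot priors named numeric: per-diagnosis prior probability in (0,1).
#' @slot version schema version tag.
#' @export
setClass("KnowledgeGraph",
  representation(nodes = "data.frame", edges = "data.frame",
                 priors = "numeric", version = "character"))

#' DiagnosisResult: posterior disease probability with contributions
#'
#' @slot pKC posterior probability of early keratoconus in [0,1].
#' @slot pSource \code{"symbolic"} or \code{"fused"}.
#' @slot contributions data.frame of per-rule contributions (w * a), sorted
#'   decreasing.
#' @slot eyeId identifier.
#' @export
setClass("DiagnosisResult",
  representation(pKC = "numeric", pSource = "character",
                 contributions = "data.frame", eyeId = "character"))

setValidity("DiagnosisResult", function(object) {
  if (!num1(object@pKC) || object@pKC < 0 || object@pKC > 1)
    "pKC must be a probability in [0,1]" else TRUE
})

#' DecisionResult: refractive-surgery eligibility decision
#'
#' @slot eligibility \code{"candidate"} or \code{"contraindicated"}.
#' @slot triggers data.frame of hard contraindication rules that fired.
#' @slot tauD decision threshold on the posterior that was applied.
#' @slot eyeId identifier.
#' @export
setClass("DecisionResult",
  representation(eligibility = "character", triggers = "data.frame",
                 tauD = "numeric", eyeId = "character"))

#' ReasoningTrace: machine-readable inference chain for one eye
#'
#' Ordered stages: (1) measured parameters, (2) evaluated rules with
#' activations and fired flags, (3) posterior computation terms, (4) decision
#' rationale. Values are exact copies of the numbers used in inference (no
#' re-rounding); the trace serializes losslessly to JSON.
#'
#' @slot eyeId identifier common to all stages.
#' @slot parameters named list of measured/derived parameter values.
#' @slot rules data.frame of rule evaluations (stage 2).
#' @slot posterior list: prior, terms, p_kc, source (stage 3).
#' @slot decision list: eligibility, triggers, tau_d (stage 4).
#' @slot version trace schema version.
#' @export
setClass("ReasoningTrace",
  representation(eyeId = "character", parameters = "list", rules = "data.frame",
                 posterior = "list", decision = "list", version = "character"),
  prototype(version = "1.0"))

#' TrainedEncoder: compact convolutional-transformer map encoder
#'
#' Opaque parameter set of the trained CNN-ViT-style curvature-map encoder
#' together with the jointly learned diagnosis-node embedding table, the
#' training history and a snapshot of the configuration used.
#'
#' @slot params named list of parameter matrices (includes the node table).
#' @slot config the [encoderConfig()] snapshot used for training.
#' @slot history data.frame: epoch, train_loss, val_loss, lr.
#' @slot classes character(2): node labels in row order of the node table.
#' @export
setClass("TrainedEncoder",
  representation(params = "list", config = "list", history = "data.frame",
                 classes = "character"))

#' ClinicalReport: rendered structured report for one eye
#'
#' @slot audience \code{"physician"} or \code{"patient"}.
#' @slot language language code of the rendering.
#' @slot sections named character vector of rendered sections in fixed order.
#' @slot appendix the full reasoning trace as a JSON string.
#' @slot eyeId identifier.
#' @export
setClass("ClinicalReport",
  representation(audience = "character", language = "character",
                 sections = "character", appendix = "character",
                 eyeId = "character"))
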