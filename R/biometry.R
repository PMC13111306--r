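#' @include AllClasses.R
NULL

#' Construct a ScanSet
#'
#' @param eyeId opaque eye identifier.
#' @param laterality "OD", "OS" or NA.
#' @param scans data.frame with columns \code{order} and the six scan
#'   measurement columns (see [ScanSet-class]); missing values as NA.
#' @param metadata list of opaque extra fields to preserve.
#' @return a [ScanSet-class].
#' @export
ScanSet <- function(eyeId, laterality = NA_character_, scans,
                    metadata = list()) {
  scans <- as.data.frame(scans)
  for (cl in c("order", scanParamCols()))
    if (!cl %in% names(scans)) scans[[cl]] <- NA_real_
  scans <- scans[, c("order", scanParamCols()), drop = FALSE]
  for (cl in names(scans)) scans[[cl]] <- as.numeric(scans[[cl]])
  new("ScanSet", eyeId = as.character(eyeId),
      laterality = as.character(laterality), scans = scans,
      metadata = metadata)
}

#' Construct a BiometricRecord
#'
#' @param eyeId,laterality identifiers (see [ScanSet()]).
#' @param k1_D,k2_D,kmax_D keratometry, diopters.
#' @param cct_um central corneal thickness, micrometers.
#' @param axial_length_mm,acd_mm axial length / anterior chamber depth, mm.
#' @param astigmatism_D astigmatism magnitude, diopters; when NULL it is
#'   computed as \code{k2_D - k1_D}.
#' @return a [BiometricRecord-class].
#' @export
BiometricRecord <- function(eyeId, laterality = NA_character_,
                            k1_D = NA_real_, k2_D = NA_real_,
                            kmax_D = NA_real_, cct_um = NA_real_,
                            axial_length_mm = NA_real_, acd_mm = NA_real_,
                            astigmatism_D = NULL) {
  if (is.null(astigmatism_D))
    astigmatism_D <- if (is.na(k1_D) || is.na(k2_D)) NA_real_ else k2_D - k1_D
  new("BiometricRecord", eyeId = as.character(eyeId),
      laterality = as.character(laterality),
      k1_D = as.numeric(k1_D), k2_D = as.numeric(k2_D),
      kmax_D = as.numeric(kmax_D), cct_um = as.numeric(cct_um),
      axial_length_mm = as.numeric(axial_length_mm),
      acd_mm = as.numeric(acd_mm), astigmatism_D = as.numeric(astigmatism_D))
}

#' Default plausibility windows for record quality control
#'
#' Generous physiologic ranges; every bound is overridable. Keratometry
#' windows apply to K1, K2 and Kmax alike.
#'
#' @param k_D,cct_um,axial_length_mm,acd_mm numeric(2) c(lo, hi) windows in
#'   the parameter's units.
#' @return a named list of windows consumed by [validateRecord()].
#' @export
qcWindows <- function(k_D = c(35, 60), cct_um = c(350, 700),
                      axial_length_mm = c(19, 32), acd_mm = c(1.5, 5.0)) {
  stopifnot(length(k_D) == 2, length(cct_um) == 2,
            length(axial_length_mm) == 2, length(acd_mm) == 2)
  list(k_D = as.numeric(k_D), cct_um = as.numeric(cct_um),
       axial_length_mm = as.numeric(axial_length_mm),
       acd_mm = as.numeric(acd_mm), kmax_slack_D = 0.5)
}

#' Parse structured biometric records into ScanSets
#'
#' Reads the documented per-eye biometry schema: a JSON file holding a
#' top-level list of objects \code{{eye_id, laterality, scans: [{order,
#' k1_D, k2_D, kmax_D, cct_um, axial_length_mm, acd_mm}]}}, or an equivalent
#' CSV dialect with one row per scan (UTF-8, header required, '.' decimal
#' separator, columns \code{eye_id, laterality, order} plus the six
#' measurements). Unknown fields are preserved as opaque metadata; missing
#' measurements become NA, never zero.
#'
#' @param path input file path.
#' @param format "auto" (by extension), "json" or "csv".
#' @return a list of [ScanSet-class], one per eye, in file order.
#' @export
parseRecords <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "json") parseRecordsJSON(path) else parseRecordsCSV(path)
}

parseRecordsJSON <- function(path) {
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("invalid JSON in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (!is.list(raw)) stop("schema error: top level must be a list of eye records")
  lapply(seq_along(raw), function(i) {
    rec <- raw[[i]]
    if (is.null(rec$eye_id))
      stop(sprintf("schema error: record %d is missing field 'eye_id'", i))
    if (is.null(rec$scans) || !length(rec$scans))
      stop(sprintf("schema error: record '%s' is missing field 'scans'", rec$eye_id))
    rows <- lapply(rec$scans, function(sc) {
      out <- lapply(c("order", scanParamCols()),
                    function(f) as.numeric(sc[[f]] %||% NA_real_))
      names(out) <- c("order", scanParamCols())
      as.data.frame(out)
    })
    scans <- do.call(rbind, rows)
    if (anyDuplicated(scans$order))
      stop(sprintf("duplicate acquisition_order in record '%s'", rec$eye_id))
    meta <- rec[setdiff(names(rec), c("eye_id", "laterality", "scans"))]
    ScanSet(rec$eye_id, rec$laterality %||% NA_character_, scans, meta)
  })
}

parseRecordsCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("eye_id", "order")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("schema error: CSV is missing required column(s): ",
         paste(miss, collapse = ", "))
  for (cl in scanParamCols()) if (!cl %in% names(df)) df[[cl]] <- NA_real_
  extra <- setdiff(names(df), c("eye_id", "laterality", "order", scanParamCols()))
  ids <- unique(df$eye_id)
  lapply(ids, function(id) {
    sub <- df[df$eye_id == id, , drop = FALSE]
    if (anyDuplicated(sub$order))
      stop(sprintf("duplicate acquisition_order in record '%s'", id))
    lat <- if ("laterality" %in% names(sub)) sub$laterality[1] else NA_character_
    meta <- if (length(extra)) list(extra_columns = sub[, extra, drop = FALSE]) else list()
    ScanSet(id, lat, sub[, c("order", scanParamCols())], meta)
  })
}

#' Aggregate repeated scans into one biometric record
#'
#' Each parameter of the final record is the median over the scans in which
#' it is present, taken per parameter independently; the astigmatism
#' magnitude is the median of the per-scan steep-minus-flat difference
#' (K2 - K1). With the default three scans the median rejects a single
#' outlying acquisition. A parameter missing in every scan propagates as NA
#' (caught downstream by [validateRecord()]).
#'
#' @param s a [ScanSet-class] with at least one scan.
#' @return a [BiometricRecord-class].
#' @export
aggregateScans <- function(s) {
  stopifnot(is(s, "ScanSet"))
  sc <- s@scans
  med <- function(x) if (all(is.na(x))) NA_real_ else stats::median(x, na.rm = TRUE)
  vals <- vapply(scanParamCols(), function(cl) med(sc[[cl]]), numeric(1))
  astig <- med(sc$k2_D - sc$k1_D)
  BiometricRecord(s@eyeId, s@laterality,
                  k1_D = vals[["k1_D"]], k2_D = vals[["k2_D"]],
                  kmax_D = vals[["kmax_D"]], cct_um = vals[["cct_um"]],
                  axial_length_mm = vals[["axial_length_mm"]],
                  acd_mm = vals[["acd_mm"]], astigmatism_D = astig)
}

#' Quality-control a biometric record
#'
#' Mirrors the cohort-level exclusion logic for incomplete or implausible
#' reports: a record is excluded with reason \code{incomplete} if any of the
#' seven parameters is missing, \code{implausible_range} if a present value
#' falls outside its plausibility window, and \code{inconsistent} if
#' K2 < K1, Kmax < K2 - 0.5 D, or the astigmatism magnitude is negative.
#' Always returns a result; never throws.
#'
#' @param r a [BiometricRecord-class].
#' @param qc plausibility windows from [qcWindows()].
#' @return a [QCResult-class].
#' @export
validateRecord <- function(r, qc = qcWindows()) {
  stopifnot(is(r, "BiometricRecord"))
  reasons <- character(); detail <- character()
  vals <- vapply(recordParamCols(), function(p) slot(r, p), numeric(1))
  if (anyNA(vals)) {
    reasons <- c(reasons, "incomplete")
    detail <- c(detail, paste0("missing parameter(s): ",
                               paste(names(vals)[is.na(vals)], collapse = ", ")))
  }
  windows <- list(k1_D = qc$k_D, k2_D = qc$k_D, kmax_D = qc$k_D,
                  cct_um = qc$cct_um, axial_length_mm = qc$axial_length_mm,
                  acd_mm = qc$acd_mm)
  bad <- character()
  for (p in names(windows)) {
    v <- vals[[p]]; w <- windows[[p]]
    if (!is.na(v) && (v < w[1] || v > w[2]))
      bad <- c(bad, sprintf("%s = %g outside [%g, %g]", p, v, w[1], w[2]))
  }
  if (length(bad)) {
    reasons <- c(reasons, "implausible_range")
    detail <- c(detail, paste(bad, collapse = "; "))
  }
  inc <- character()
  if (!is.na(vals[["k1_D"]]) && !is.na(vals[["k2_D"]]) &&
      vals[["k2_D"]] < vals[["k1_D"]])
    inc <- c(inc, "K2 < K1")
  if (!is.na(vals[["k2_D"]]) && !is.na(vals[["kmax_D"]]) &&
      vals[["kmax_D"]] < vals[["k2_D"]] - qc$kmax_slack_D)
    inc <- c(inc, sprintf("Kmax < K2 - %g D", qc$kmax_slack_D))
  if (!is.na(vals[["astigmatism_D"]]) && vals[["astigmatism_D"]] < 0)
    inc <- c(inc, "negative astigmatism magnitude")
  if (length(inc)) {
    reasons <- c(reasons, "inconsistent")
    detail <- c(detail, paste(inc, collapse = "; "))
  }
  new("QCResult", status = if (length(reasons)) "excluded" else "pass",
      reasons = reasons, detail = detail)
}

#' Derive rule-facing features from a record
#'
#' Computes mean keratometry (K1+K2)/2, the keratometric astigmatism
#' difference K2-K1, and the Kmax excess over mean keratometry. Inputs are
#' expected to have passed QC; a missing keratometry value is an error.
#'
#' @param r a [BiometricRecord-class].
#' @return a [DerivedFeatures-class].
#' @export
deriveFeatures <- function(r) {
  stopifnot(is(r, "BiometricRecord"))
  if (is.na(r@k1_D) || is.na(r@k2_D) || is.na(r@kmax_D))
    stop("cannot derive features: missing keratometry parameter(s) in record '",
         r@eyeId, "'")
  mk <- (r@k1_D + r@k2_D) / 2
  new("DerivedFeatures", mean_k_D = mk, astig_kdiff_D = r@k2_D - r@k1_D,
      kmax_excess_D = r@kmax_D - mk)
}
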