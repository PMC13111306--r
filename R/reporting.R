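#' @include AllClasses.R inference.R
NULL

#' Load a report template catalog
#'
#' Template catalogs are versioned YAML data files, one per language;
#' English (\code{en}) and Simplified Chinese (\code{zh}) ship with the
#' package and any language can be added by dropping in another catalog.
#' Each catalog defines every section of both the physician and the patient
#' report, parameter labels with units, and direction words; placeholders
#' use the \code{{name}} grammar and are resolved from a reasoning trace.
#'
#' @param lang language code.
#' @param dir directory of catalogs (defaults to the shipped ones).
#' @return the catalog as a named list.
#' @export
loadTemplateCatalog <- function(lang = "en", dir = NULL) {
  dir <- dir %||% system.file("extdata", "templates", package = "CornealKG",
                              mustWork = TRUE)
  avail <- sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$"))
  if (!lang %in% avail)
    stop("unknown language '", lang, "'; available: ",
         paste(avail, collapse = ", "))
  yaml::read_yaml(file.path(dir, paste0(lang, ".yaml")))
}

#' Jargon blocklist for patient-facing text
#'
#' Tokens that must never appear in a patient summary; maintained here and
#' linted by the test suite.
#'
#' @return character vector of forbidden tokens.
#' @export
jargonBlocklist <- function() {
  c("noisy-OR", "posterior", "logit", "Bayesian", "activation", "rule_id",
    "threshold", "AUC", "sensitivity", "specificity")
}

fillTemplate <- function(tpl, values) {
  for (nm in names(values))
    tpl <- gsub(paste0("{", nm, "}"), values[[nm]], tpl, fixed = TRUE)
  tpl
}

fmtValue <- function(feature, v) {
  if (grepl("_um$", feature)) sprintf("%.1f", v) else sprintf("%.2f", v)
}

# appendix: the full trace JSON plus the exact formatted strings used in the
# rendered report, so every displayed number is recoverable verbatim
buildAppendix <- function(t, rendered) {
  trace <- jsonlite::fromJSON(traceToJSON(t), simplifyVector = TRUE)
  as.character(jsonlite::toJSON(list(trace = trace,
                                     rendered_values = rendered),
                                auto_unbox = TRUE, digits = I(17),
                                na = "null"))
}

#' Generate the physician-facing structured report
#'
#' Deterministic rendering of a reasoning trace into the fixed section
#' order measurements, evidence, probability, decision, caveats. Every
#' fired rule is rendered with its identifier, the observed value, the
#' threshold and the direction; the posterior is printed to three decimals.
#' The full trace (plus every formatted number used) is embedded as a JSON
#' appendix. Identical traces render byte-identically.
#'
#' @param t a [ReasoningTrace-class].
#' @param lang language code present in the catalog directory.
#' @param catalog optional pre-loaded catalog (overrides \code{lang}).
#' @return a [ClinicalReport-class].
#' @export
generatePhysicianReport <- function(t, lang = "en", catalog = NULL) {
  cat_ <- catalog %||% loadTemplateCatalog(lang)
  ph <- cat_$physician
  rendered <- list()
  putv <- function(key, txt) { rendered[[key]] <<- txt; txt }
  plab <- function(f) cat_$params[[f]]$label %||% f
  punit <- function(f) cat_$params[[f]]$unit %||% ""
  mLines <- vapply(names(t@parameters), function(f) {
    v <- putv(paste0("param.", f), fmtValue(f, t@parameters[[f]]))
    fillTemplate(ph$measurement_line,
                 list(label = plab(f), value = v, unit = punit(f)))
  }, character(1))
  measurements <- paste(mLines, collapse = "\n")
  fired <- t@rules[t@rules$fired, , drop = FALSE]
  evidence <- if (nrow(fired) == 0) ph$no_rules else
    paste(vapply(seq_len(nrow(fired)), function(i) {
      r <- fired[i, ]
      fillTemplate(ph$rule_line, list(
        rule_id = r$rule_id, label = plab(r$feature),
        value = putv(paste0("rule.", r$rule_id, ".value"),
                     fmtValue(r$feature, r$value)),
        unit = punit(r$feature),
        direction = cat_$direction_words[[r$direction]],
        threshold = putv(paste0("rule.", r$rule_id, ".threshold"),
                         fmtValue(r$feature, r$threshold)),
        activation = putv(paste0("rule.", r$rule_id, ".activation"),
                          sprintf("%.3f", r$activation))))
    }, character(1)), collapse = "\n")
  probability <- fillTemplate(ph$probability_line, list(
    p = putv("posterior.p_kc", sprintf("%.3f", t@posterior$p_kc)),
    prior = putv("posterior.prior", sprintf("%.3f", t@posterior$prior))))
  decTpl <- if (t@decision$eligibility == "contraindicated")
    ph$decision_contraindicated else ph$decision_candidate
  decision <- fillTemplate(decTpl, list(
    tau_d = putv("decision.tau_d", sprintf("%.2f", t@decision$tau_d))))
  trig <- t@decision$triggers
  if (!is.null(trig) && nrow(trig)) {
    decision <- paste(c(decision, vapply(seq_len(nrow(trig)), function(i) {
      r <- trig[i, ]
      fillTemplate(ph$trigger_line, list(
        rule_id = r$rule_id, label = plab(r$feature),
        value = putv(paste0("trigger.", r$rule_id, ".value"),
                     fmtValue(r$feature, r$value)),
        unit = punit(r$feature),
        direction = cat_$direction_words[[r$direction]],
        threshold = putv(paste0("trigger.", r$rule_id, ".threshold"),
                         fmtValue(r$feature, r$threshold))))
    }, character(1))), collapse = "\n")
  }
  sections <- c(
    title = fillTemplate(ph$title, list(eye_id = t@eyeId)),
    measurements = paste(ph$measurements_header, measurements, sep = "\n"),
    evidence = paste(ph$evidence_header, evidence, sep = "\n"),
    probability = paste(ph$probability_header, probability, sep = "\n"),
    decision = paste(ph$decision_header, decision, sep = "\n"),
    caveats = paste(ph$caveats_header, ph$caveats, sep = "\n"))
  new("ClinicalReport", audience = "physician", language = cat_$language,
      sections = sections, appendix = buildAppendix(t, rendered),
      eyeId = t@eyeId)
}

#' Generate the simplified patient-facing summary
#'
#' Maps the keratoconus posterior to lay risk bands — low below 0.1,
#' moderate from 0.1 up to the decision threshold, elevated at or above it
#' (so the elevated band starts exactly at \eqn{\tau_d}) — and renders the
#' matching plain-language wording. Contains no rule identifiers, no raw
#' probabilities and no token from [jargonBlocklist()].
#'
#' @inheritParams generatePhysicianReport
#' @return a [ClinicalReport-class].
#' @export
generatePatientSummary <- function(t, lang = "en", catalog = NULL) {
  cat_ <- catalog %||% loadTemplateCatalog(lang)
  pt <- cat_$patient
  p <- t@posterior$p_kc
  tauD <- t@decision$tau_d
  band <- if (p < 0.1) "band_low" else if (p < tauD) "band_moderate"
          else "band_elevated"
  decTpl <- if (t@decision$eligibility == "contraindicated")
    pt$decision_contraindicated else pt$decision_candidate
  sections <- c(
    title = fillTemplate(pt$title, list(eye_id = t@eyeId)),
    findings = paste(pt$findings_header, pt$findings, sep = "\n"),
    risk = paste(pt$risk_header, pt[[band]], sep = "\n"),
    decision = paste(pt$decision_header, decTpl, sep = "\n"),
    caveats = paste(pt$caveats_header, pt$caveats, sep = "\n"))
  new("ClinicalReport", audience = "patient", language = cat_$language,
      sections = sections,
      appendix = buildAppendix(t, list(band = band)), eyeId = t@eyeId)
}

#' Render a clinical report as Markdown
#'
#' @param report a [ClinicalReport-class].
#' @param withAppendix append the JSON appendix in a fenced block.
#' @return a single Markdown string.
#' @export
reportMarkdown <- function(report, withAppendix = FALSE) {
  body <- paste(c(paste0("# ", report@sections[["title"]]),
                  report@sections[setdiff(names(report@sections), "title")]),
                collapse = "\n\n")
  if (withAppendix)
    body <- paste0(body, "\n\n```json\n", report@appendix, "\n```\n")
  body
}

#' Pluggable text-generation adapter
#'
#' Interface point for an external narrative generator (for example an LLM
#' service): the generator receives the trace JSON and the deterministic
#' report as grounding context and returns free text. No generator is
#' configured by default and none is required — the deterministic report is
#' the fallback on absence or failure, with a logged notice. The core test
#' suite only ever uses stub generators; no network access is involved.
#'
#' @param t a [ReasoningTrace-class].
#' @param generator NULL, or a function(trace_json, deterministic_report)
#'   returning a character scalar.
#' @param lang,audience passed to the deterministic renderer.
#' @return character: the generated text, or the deterministic Markdown
#'   report when no generator is available or it fails.
#' @export
renderWithAdapter <- function(t, generator = NULL, lang = "en",
                              audience = c("physician", "patient")) {
  audience <- match.arg(audience)
  det <- reportMarkdown(
    if (audience == "physician") generatePhysicianReport(t, lang)
    else generatePatientSummary(t, lang))
  if (is.null(generator)) return(det)
  out <- tryCatch(generator(traceToJSON(t), det), error = function(e) {
    message("text generator failed (", conditionMessage(e),
            "); falling back to the deterministic report")
    NULL
  })
  if (is.null(out) || !is.character(out) || length(out) != 1L) det else out
}
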