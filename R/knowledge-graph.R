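#' @include AllClasses.R biometry.R
NULL

GRAPH_SCHEMA_VERSION <- "1.0"
NODE_CATEGORIES <- c("parameter", "diagnosis", "decision")

edgeTemplate <- function() {
  data.frame(source = character(), target = character(), weight = numeric(),
             rule_id = character(), feature = character(),
             direction = character(), threshold = numeric(),
             softness = numeric(), stringsAsFactors = FALSE)
}

#' Construct a knowledge graph from components
#'
#' Low-level constructor; most callers want [buildDefaultGraph()] or
#' [loadGraph()]. No validation is applied here — use [validateGraph()].
#'
#' @param nodes data.frame: node_id, category, label, label_en, label_zh.
#' @param edges data.frame: source, target, weight and (for rule-bearing
#'   edges) rule_id, feature, direction, threshold, softness.
#' @param priors named numeric of per-diagnosis prior probabilities.
#' @param version schema version string.
#' @return a [KnowledgeGraph-class].
#' @export
KnowledgeGraph <- function(nodes, edges, priors,
                           version = GRAPH_SCHEMA_VERSION) {
  for (cl in names(edgeTemplate()))
    if (!cl %in% names(edges))
      edges[[cl]] <- rep(if (is.numeric(edgeTemplate()[[cl]])) NA_real_
                         else NA_character_, nrow(edges))
  new("KnowledgeGraph", nodes = as.data.frame(nodes),
      edges = as.data.frame(edges)[, names(edgeTemplate())],
      priors = priors, version = version)
}

#' Build the default clinical corneal knowledge graph
#'
#' Loads the graph shipped with the package: eight biometric parameter
#' nodes (K1, K2, Kmax, CCT, axial length, ACD, astigmatism, I-S
#' asymmetry), two diagnosis nodes (early keratoconus, normal cornea) and
#' two decision nodes (surgery candidate / contraindicated). The
#' rule-bearing edges encode the screening heuristics of elevated Kmax,
#' reduced pachymetry, high astigmatism magnitude and inferior-superior
#' asymmetry toward early keratoconus, plus a hard pachymetry
#' contraindication for refractive surgery. Every threshold, softness,
#' weight and the diagnosis prior is configuration, not code: pass
#' \code{rules} and/or \code{prior} to override, or edit the graph file.
#'
#' @param rules optional named list of per-rule overrides, e.g.
#'   \code{list(R1 = list(threshold = 48, weight = 0.7))}.
#' @param prior optional override for the early-keratoconus prior in (0,1).
#' @param path path to a graph JSON file (defaults to the shipped graph).
#' @return a validated [KnowledgeGraph-class].
#' @export
buildDefaultGraph <- function(rules = NULL, prior = NULL, path = NULL) {
  path <- path %||% system.file("extdata", "graph", "default_graph.json",
                                package = "CornealKG", mustWork = TRUE)
  g <- loadGraph(path)
  if (!is.null(rules)) {
    for (rid in names(rules)) {
      i <- which(g@edges$rule_id == rid)
      if (!length(i)) stop("unknown rule_id in overrides: ", rid)
      for (fld in names(rules[[rid]]))
        g@edges[[fld]][i] <- rules[[rid]][[fld]]
    }
  }
  if (!is.null(prior)) {
    if (!num1(prior) || prior <= 0 || prior >= 1)
      stop("prior must be in (0, 1)")
    g@priors[["early_keratoconus"]] <- prior
    g@priors[["normal_cornea"]] <- 1 - prior
  }
  v <- validateGraph(g)
  if (length(v)) stop("default graph invalid after overrides: ",
                      paste(v, collapse = "; "))
  g
}

#' Validate a knowledge graph
#'
#' Returns every violation of the graph contract as data (never throws):
#' unknown or duplicate node ids, unknown categories, dangling edge
#' references, weights outside [0,1], layer-breaking edges (only
#' parameter->diagnosis, diagnosis->decision and parameter->decision are
#' allowed), cycles, rule-less parameter-source edges, malformed rules and
#' missing or out-of-range diagnosis priors.
#'
#' @param g a [KnowledgeGraph-class].
#' @return character vector of violations; empty when the graph is valid.
#' @export
validateGraph <- function(g) {
  v <- character()
  nd <- g@nodes; ed <- g@edges
  if (anyDuplicated(nd$node_id))
    v <- c(v, paste0("duplicate node_id: ",
                     paste(unique(nd$node_id[duplicated(nd$node_id)]), collapse = ", ")))
  badcat <- setdiff(unique(nd$category), NODE_CATEGORIES)
  if (length(badcat))
    v <- c(v, paste0("unknown node category: ", paste(badcat, collapse = ", ")))
  cat_of <- stats::setNames(nd$category, nd$node_id)
  for (i in seq_len(nrow(ed))) {
    e <- ed[i, ]
    tag <- sprintf("edge %s->%s", e$source, e$target)
    if (!e$source %in% nd$node_id || !e$target %in% nd$node_id) {
      v <- c(v, paste0(tag, ": dangling node reference"))
      next
    }
    if (is.na(e$weight) || e$weight < 0 || e$weight > 1)
      v <- c(v, sprintf("%s: weight %s outside [0,1]", tag, format(e$weight)))
    lay <- paste(cat_of[[e$source]], cat_of[[e$target]], sep = "->")
    if (!lay %in% c("parameter->diagnosis", "diagnosis->decision",
                    "parameter->decision"))
      v <- c(v, sprintf("%s: layer-breaking edge (%s)", tag, lay))
    if (cat_of[[e$source]] == "parameter") {
      if (is.na(e$rule_id))
        v <- c(v, paste0(tag, ": parameter-source edge without a rule"))
      else {
        if (!e$direction %in% c("above", "below"))
          v <- c(v, sprintf("%s (rule %s): direction must be above/below", tag, e$rule_id))
        if (is.na(e$threshold) || !is.finite(e$threshold))
          v <- c(v, sprintf("%s (rule %s): non-finite threshold", tag, e$rule_id))
        if (is.na(e$softness) || e$softness < 0)
          v <- c(v, sprintf("%s (rule %s): softness must be >= 0", tag, e$rule_id))
      }
    }
  }
  if (nrow(ed)) {
    ig <- igraph::graph_from_data_frame(ed[, c("source", "target")],
                                        vertices = unique(c(nd$node_id, ed$source, ed$target)))
    if (!igraph::is_dag(ig)) v <- c(v, "graph contains a cycle")
  }
  for (d in nd$node_id[nd$category == "diagnosis"]) {
    p <- g@priors[d]
    if (is.na(p) || p <= 0 || p >= 1)
      v <- c(v, sprintf("diagnosis node %s: missing or out-of-range prior", d))
  }
  v
}

#' Save / load a knowledge graph as canonical JSON
#'
#' The JSON serialization is canonical (objects with alphabetically sorted
#' keys, explicit version tag), so \code{loadGraph(saveGraph(g))} is the
#' identity and file diffs are meaningful. \code{loadGraph} refuses files
#' with a mismatched schema version or unknown node categories and enforces
#' [validateGraph()] on load, so any graph that loads is valid.
#'
#' @param g a [KnowledgeGraph-class].
#' @param path file path.
#' @return \code{saveGraph}: the path, invisibly. \code{loadGraph}: a
#'   [KnowledgeGraph-class].
#' @export
saveGraph <- function(g, path) {
  nodes <- lapply(seq_len(nrow(g@nodes)), function(i) {
    r <- g@nodes[i, ]
    list(category = r$category, label = r$label, label_en = r$label_en,
         label_zh = r$label_zh, node_id = r$node_id)
  })
  ord <- order(vapply(nodes, `[[`, character(1), "node_id"))
  nodes <- nodes[ord]
  edges <- lapply(seq_len(nrow(g@edges)), function(i) {
    e <- g@edges[i, ]
    rule <- if (is.na(e$rule_id)) NULL else
      list(direction = e$direction, feature = e$feature, rule_id = e$rule_id,
           softness = e$softness, threshold = e$threshold)
    list(rule = rule, source = e$source, target = e$target, weight = e$weight)
  })
  ord <- order(vapply(edges, function(e) paste(e$source, e$target), character(1)))
  edges <- edges[ord]
  pr <- as.list(g@priors[order(names(g@priors))])
  writeJSONCanonical(list(edges = edges, nodes = nodes, priors = pr,
                          version = g@version), path)
  invisible(path)
}

#' @rdname saveGraph
#' @export
loadGraph <- function(path) {
  if (!file.exists(path)) stop("graph file not found: ", path)
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("invalid graph JSON: ",
                                           conditionMessage(e), call. = FALSE))
  if (!identical(raw$version, GRAPH_SCHEMA_VERSION))
    stop("graph schema version mismatch: file has '",
         raw$version %||% "<none>", "', expected '", GRAPH_SCHEMA_VERSION, "'")
  nodes <- do.call(rbind, lapply(raw$nodes, function(nd) {
    if (!is.null(nd$category) && !nd$category %in% NODE_CATEGORIES)
      stop("graph schema error: unknown node category '", nd$category,
           "' for node '", nd$node_id %||% "?", "'")
    data.frame(node_id = nd$node_id, category = nd$category,
               label = nd$label %||% nd$node_id,
               label_en = nd$label_en %||% nd$label %||% nd$node_id,
               label_zh = nd$label_zh %||% nd$label %||% nd$node_id,
               stringsAsFactors = FALSE)
  }))
  edges <- do.call(rbind, lapply(raw$edges, function(e) {
    r <- e$rule
    data.frame(source = e$source, target = e$target,
               weight = as.numeric(e$weight),
               rule_id = r$rule_id %||% NA_character_,
               feature = r$feature %||% NA_character_,
               direction = r$direction %||% NA_character_,
               threshold = as.numeric(r$threshold %||% NA_real_),
               softness = as.numeric(r$softness %||% NA_real_),
               stringsAsFactors = FALSE)
  }))
  priors <- unlist(raw$priors)
  g <- KnowledgeGraph(nodes, edges, priors, version = raw$version)
  v <- validateGraph(g)
  if (length(v)) stop("graph file fails validation: ", paste(v, collapse = "; "))
  g
}

#' Export a knowledge graph to GraphML for visualization
#'
#' @param g a [KnowledgeGraph-class].
#' @param path output .graphml path.
#' @return the path, invisibly.
#' @export
exportGraphML <- function(g, path) {
  ig <- igraph::graph_from_data_frame(
    g@edges[, c("source", "target", "weight", "rule_id")],
    vertices = g@nodes[, c("node_id", "category", "label")])
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' Evaluate threshold rules against a record (evidence activation)
#'
#' For every rule-bearing edge of the graph, resolves the rule's feature
#' from the record, the derived features or the optional map indices, and
#' computes a soft activation \eqn{a = \sigma((x - \tau)/s)} for direction
#' \code{above} (mirrored for \code{below}), where \eqn{\sigma} is the
#' logistic function and \eqn{s} the softness scale in the feature's units.
#' A softness of 0 is a hard step: activation 1 strictly past the
#' threshold, 0.5 at it, 0 otherwise. Rules on the inferior-superior
#' asymmetry are skipped with a notice when no map indices are supplied;
#' any other unresolvable feature is an error naming the rule.
#'
#' @param r a QC-passing [BiometricRecord-class].
#' @param f the matching [DerivedFeatures-class].
#' @param m optional map indices from [computeMapIndices()].
#' @param g a [KnowledgeGraph-class].
#' @return an evidence-activation data.frame (one row per evaluated rule:
#'   rule_id, feature, value, direction, threshold, softness, activation,
#'   weight, source, target) with an \code{eyeId} attribute.
#' @export
activateEvidence <- function(r, f, m = NULL, g) {
  stopifnot(is(r, "BiometricRecord"), is(f, "DerivedFeatures"),
            is(g, "KnowledgeGraph"))
  feats <- list(
    k1_D = r@k1_D, k2_D = r@k2_D, kmax_D = r@kmax_D, cct_um = r@cct_um,
    axial_length_mm = r@axial_length_mm, acd_mm = r@acd_mm,
    astigmatism_D = r@astigmatism_D, mean_k_D = f@mean_k_D,
    astig_kdiff_D = f@astig_kdiff_D, kmax_excess_D = f@kmax_excess_D)
  mapFeats <- c("is_asymmetry_D", "max_power_D")
  if (!is.null(m)) {
    feats$is_asymmetry_D <- m$is_asymmetry_D
    feats$max_power_D <- m$max_power_D
  }
  ed <- g@edges[!is.na(g@edges$rule_id), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(ed))) {
    e <- ed[i, ]
    x <- feats[[e$feature]]
    if (is.null(x) || is.na(x)) {
      if (e$feature %in% mapFeats && is.null(m)) {
        message("activateEvidence: skipping rule ", e$rule_id,
                " (no curvature-map indices supplied)")
        next
      }
      stop("rule ", e$rule_id, ": feature '", e$feature,
           "' cannot be resolved for eye '", r@eyeId, "'")
    }
    a <- ruleActivation(x, e$threshold, e$direction, e$softness)
    rows[[length(rows) + 1L]] <- data.frame(
      rule_id = e$rule_id, feature = e$feature, value = x,
      direction = e$direction, threshold = e$threshold,
      softness = e$softness, activation = a, weight = e$weight,
      source = e$source, target = e$target, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    cbind(edgeTemplate()[0, ], data.frame(value = numeric(),
                                          activation = numeric()))
  attr(out, "eyeId") <- r@eyeId
  out
}

#' @rdname activateEvidence
#' @param x observed feature value.
#' @param threshold rule threshold in the feature's units.
#' @param direction "above" or "below".
#' @param softness logistic scale (same units); 0 means a hard step.
#' @export
ruleActivation <- function(x, threshold, direction, softness) {
  stopifnot(direction %in% c("above", "below"), softness >= 0)
  d <- if (direction == "above") x - threshold else threshold - x
  if (softness == 0) {
    ifelse(d > 0, 1, ifelse(d == 0, 0.5, 0))
  } else {
    stats::plogis(d / softness)
  }
}
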