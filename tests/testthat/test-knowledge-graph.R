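test_that("the default graph has the expected layered clinical structure", {
  g <- buildDefaultGraph()
  expect_setequal(unique(graphNodes(g)$category),
                  c("parameter", "diagnosis", "decision"))
  ed <- graphEdges(g)
  kmaxRule <- ed[!is.na(ed$feature) & ed$feature == "kmax_D" &
                   ed$direction == "above", ]
  expect_gte(nrow(kmaxRule), 1)
  expect_true(all(kmaxRule$target == "early_keratoconus"))
  expect_length(validateGraph(g), 0)
  # priors present and complementary for the binary screening task
  pr <- graphPriors(g)
  expect_equal(unname(pr["early_keratoconus"] + pr["normal_cornea"]), 1)
})

test_that("config overrides reach the rules without touching code", {
  g <- buildDefaultGraph(rules = list(R1 = list(threshold = 48.5, weight = 0.7)),
                         prior = 0.1)
  e <- graphEdges(g)
  expect_equal(e$threshold[which(e$rule_id == "R1")], 48.5)
  expect_equal(e$weight[which(e$rule_id == "R1")], 0.7)
  expect_equal(unname(graphPriors(g)["early_keratoconus"]), 0.1)
  expect_error(buildDefaultGraph(rules = list(R99 = list(threshold = 1))),
               "R99")
})

test_that("validateGraph reports violations as data, never throws", {
  g <- buildDefaultGraph()
  bad <- g
  bad@edges$weight[1] <- 1.5
  v <- validateGraph(bad)
  expect_length(v, 1)
  expect_match(v, "weight")
  # layer-breaking edge: decision -> parameter
  bad2 <- g
  bad2@edges <- rbind(bad2@edges, data.frame(
    source = "surgery_candidate", target = "K1", weight = 0.5,
    rule_id = NA, feature = NA, direction = NA, threshold = NA,
    softness = NA))
  expect_true(any(grepl("layer-breaking", validateGraph(bad2))))
  # rule-less parameter-source edge
  bad3 <- g
  bad3@edges$rule_id[1] <- NA
  expect_true(any(grepl("without a rule", validateGraph(bad3))))
  # dangling reference and missing prior
  bad4 <- g
  bad4@edges$target[1] <- "ghost"
  expect_true(any(grepl("dangling", validateGraph(bad4))))
  bad5 <- g
  bad5@priors <- bad5@priors["normal_cornea"]
  expect_true(any(grepl("prior", validateGraph(bad5))))
})

test_that("graph JSON serialization is a canonical identity round trip", {
  g <- buildDefaultGraph()
  f <- withr::local_tempfile(fileext = ".json")
  saveGraph(g, f)
  g2 <- loadGraph(f)
  expect_equal(graphPriors(g2), graphPriors(g))
  expect_setequal(graphNodes(g2)$node_id, graphNodes(g)$node_id)
  e1 <- graphEdges(g); e1 <- e1[order(e1$source, e1$target), ]
  e2 <- graphEdges(g2); e2 <- e2[order(e2$source, e2$target), ]
  rownames(e1) <- rownames(e2) <- NULL
  expect_equal(e2, e1)
  # canonical: saving twice gives byte-identical files
  f2 <- withr::local_tempfile(fileext = ".json")
  saveGraph(g2, f2)
  saveGraph(g, f)
  expect_identical(readLines(f), readLines(f2))
})

test_that("loading rejects version mismatches and unknown categories", {
  g <- buildDefaultGraph()
  f <- withr::local_tempfile(fileext = ".json")
  saveGraph(g, f)
  txt <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  txt$version <- "0.9"
  jsonlite::write_json(txt, f, auto_unbox = TRUE, digits = NA)
  expect_error(loadGraph(f), "version")
  txt$version <- "1.0"
  txt$nodes[[1]]$category <- "banana"
  jsonlite::write_json(txt, f, auto_unbox = TRUE, digits = NA)
  expect_error(loadGraph(f), "banana")
})

test_that("GraphML export preserves node and edge counts", {
  g <- buildDefaultGraph()
  f <- withr::local_tempfile(fileext = ".graphml")
  exportGraphML(g, f)
  ig <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(ig), nrow(graphNodes(g)))
  expect_equal(igraph::ecount(ig), nrow(graphEdges(g)))
})

test_that("rule activation follows the logistic form and its hard limit", {
  # logistic midpoint: x = tau gives 0.5 for any softness > 0
  for (s in c(0.1, 1, 10))
    expect_equal(ruleActivation(47, 47, "above", s), 0.5)
  # hard step: 1 strictly past tau, 0.5 at tau, 0 otherwise
  expect_equal(ruleActivation(50.14, 47, "above", 0), 1)
  expect_equal(ruleActivation(47, 47, "above", 0), 0.5)
  expect_equal(ruleActivation(46.9, 47, "above", 0), 0)
  expect_equal(ruleActivation(470, 480, "below", 0), 1)
  # closed form
  expect_equal(ruleActivation(48, 47, "above", 0.5), plogis(2))
  expect_equal(ruleActivation(490, 500, "below", 10), plogis(1))
})

test_that("activation is monotone in the feature for both directions", {
  xs <- seq(40, 55, by = 0.25)
  for (s in c(0.3, 1)) {
    up <- ruleActivation(xs, 47, "above", s)
    expect_true(all(diff(up) >= 0))
    dn <- ruleActivation(xs, 47, "below", s)
    expect_true(all(diff(dn) <= 0))
    expect_true(all(up >= 0 & up <= 1))
  }
  # CCT below-threshold activation grows as the cornea thins
  ccts <- seq(560, 440, by = -10)
  a <- ruleActivation(ccts, 500, "below", 10)
  expect_true(all(diff(a) > 0))
  expect_gt(a[ccts == 490][1], 0.5)
})

test_that("evidence activation resolves features and handles missing maps", {
  g <- buildDefaultGraph()
  r <- referenceMeanRecord()
  f <- deriveFeatures(r)
  expect_message(e <- activateEvidence(r, f, NULL, g), "R4")
  expect_false("R4" %in% e$rule_id)
  expect_true(all(c("R1", "R2", "R3", "R5") %in% e$rule_id))
  expect_true(all(e$activation >= 0 & e$activation <= 1))
  expect_identical(attr(e, "eyeId"), "REF001")
  # with map indices the I-S rule is evaluated too
  m <- list(is_asymmetry_D = 2.0, max_power_D = 48)
  e2 <- activateEvidence(r, f, m, g)
  expect_true("R4" %in% e2$rule_id)
  expect_gt(e2$activation[e2$rule_id == "R4"], 0.5)
  # an unresolvable non-map feature is a hard error naming the rule
  g2 <- buildDefaultGraph()
  g2@edges$feature[g2@edges$rule_id == "R1"] <- "no_such_feature"
  expect_error(activateEvidence(r, f, m, g2), "R1")
})

test_that("determinism: identical inputs give identical activations", {
  g <- buildDefaultGraph()
  r <- referenceMeanRecord()
  f <- deriveFeatures(r)
  m <- list(is_asymmetry_D = 0.4, max_power_D = 46)
  expect_identical(activateEvidence(r, f, m, g), activateEvidence(r, f, m, g))
})
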