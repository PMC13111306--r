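---
title: "Methods: knowledge-graph screening for early keratoconus"
author: "CornealKG"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: knowledge-graph screening for early keratoconus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(CornealKG)
```

This vignette is the package's own account of its models, the parameters
that matter, the numerical choices made where the design was genuinely
open, and what the synthetic benchmarks do and do not demonstrate.

## 1. Data model and quality control

A `ScanSet` holds the raw repeated acquisitions of one eye (three by
default, matching routine repeat-scan practice on optical biometers); a
`BiometricRecord` is the aggregated per-eye tuple (K1, K2, Kmax in
diopters; CCT in micrometers; axial length and ACD in millimeters;
astigmatism magnitude in diopters). Aggregation takes the **median per
parameter independently** across scans, so a single outlying acquisition
is rejected; astigmatism is the median of the per-scan K2 − K1
difference. Astigmatism is a magnitude only — the meridian axis is not
modeled anywhere in the package.

S4 validity on these classes is deliberately *structural only* (types,
positivity, unique scan order). Clinical consistency — K2 ≥ K1, Kmax ≥ K2
− 0.5 D (Kmax is a point maximum and may exceed the steep simulated
keratometry only within tolerance), astigmatism ≥ 0 — lives in
`validateRecord()`, which must be able to *inspect and flag* inconsistent
records rather than have their construction fail. QC returns one of three
exclusion reasons (`incomplete`, `implausible_range`, `inconsistent`);
missing values are explicit sentinels and are never imputed, mirroring
cohort practice of excluding incomplete reports instead of repairing
them. The plausibility windows (K in [35, 60] D, CCT in [350, 700] µm, AL
in [19, 32] mm, ACD in [1.5, 5.0] mm) are generous physiologic ranges and
are configuration (`qcWindows()`).

One record is one eye. If a caller has two eyes per patient, selecting
one eye per patient (to avoid inter-eye correlation) is the caller's
responsibility; the simulator generates independent eyes.

## 2. The synthetic cohort simulator

The simulator defines the study conditions for every benchmark in the
package; its defaults are fixed once and are not tuned to test outcomes.

**Marginal mode** draws each of the seven parameters independently from
an *untruncated* normal at the reference cohort mean/SD
(`referenceCohortStats()`: K1 43.21 ± 1.18 D, K2 44.36 ± 1.42 D, Kmax
46.02 ± 2.15 D, CCT 532.6 ± 28.4 µm, AL 24.18 ± 1.12 mm, ACD 3.21 ± 0.38
mm, astigmatism 1.15 ± 0.72 D). The published min/max are reported cohort
extremes, not distribution bounds, and are therefore not used for
truncation: truncating or re-ordering draws would bias the recovered
means (sorting K1/K2 alone shifts the K1 mean by ≈ 0.3 D), defeating the
mode's purpose, which is calibration checking of marginal statistics.
The price is that cross-parameter clinical invariants can be violated in
this mode (≈ 27% of eyes draw K2 < K1); marginal cohorts are documented
as calibration-only and are not passed through QC-dependent pipelines.

**Labeled mode** (the default) draws a two-class cohort. Both classes
share K1 ~ N(43.0, 1.0) D, AL ~ N(24.18, 1.12) mm, ACD ~ N(3.21, 0.38)
mm. The normal class draws astigmatism ~ |N(0.9, 0.5)| D, Kmax = mean K +
|N(0.8, 0.4)| D and CCT ~ N(545, 25) µm; the early-keratoconus class
astigmatism ~ |N(1.8, 0.8)| D, Kmax = mean K + max(N(4.5, 1.5), 2.5) D
and CCT ~ N(495, 25) µm — the steep-Kmax/thin-cornea signature of early
ectasia. K2 = K1 + astigmatism, and Kmax is floored at K2 because a point
maximum cannot undercut the steep meridian. The keratoconus fraction
defaults to 0.5, an arbitrary balanced benchmark choice (no prevalence is
assumed).

**Scan noise** is zero-mean Gaussian per scan and parameter (0.10 D on
keratometry, 3 µm on CCT, 0.02 mm on AL, 0.03 mm on ACD) — explicit
configuration values of the order of optical-biometer repeatability.
Within each simulated scan the flat/steep labels are reassigned after
noising (K1 = min, K2 = max), as a device labels meridians per
acquisition; this keeps per-scan astigmatism non-negative, and it is why
every labeled-mode eye passes QC through the scan-aggregation pipeline.

**Curvature maps** are rendered on a square grid (default 64 px over 9
mm, +y superior, +x temporal-for-OD) as

K(x, y) = mean K + (ΔK/2)·cos 2(θ − φ) + A·exp(−d²/2σ²)

a regular astigmatic bowtie around axis φ (default 90°, with-the-rule)
plus a Gaussian cone. Early-keratoconus eyes receive an inferior
paracentral cone — center radius ~ U(1, 2) mm, angle ~ N(270°, 20°), σ ~
U(0.8, 1.4) mm, the canonical early-KC morphology — with amplitude set so
the map peaks at the eye's Kmax at the cone apex. Pixels outside the
corneal disc carry a constant background of 38 D (the bottom of the fixed
38–52 D display scale) so every map value is finite. The simulator does
**not** emulate elevation or posterior-surface data, eyelid shadows,
tear-film artifacts or device-specific interpolation; passing benchmarks
therefore demonstrate correctness of the pipeline under idealized
morphology, not clinical performance on real maps.

## 3. The knowledge graph

The graph is a layered DAG: parameter → diagnosis, diagnosis → decision,
parameter → decision edges only. Parameter-source edges carry a threshold
rule (feature, direction, threshold τ, softness s) and a weight w ∈
[0, 1]. The shipped default graph (a JSON data file, not code) encodes:

| rule | feature | direction | τ | s | w | target |
|---|---|---|---|---|---|---|
| R1 | kmax_D | above | 47.0 D | 0.5 | 0.60 | early keratoconus |
| R2 | cct_um | below | 500 µm | 10 | 0.45 | early keratoconus |
| R3 | astig_kdiff_D | above | 2.0 D | 0.3 | 0.25 | early keratoconus |
| R4 | is_asymmetry_D | above | 1.4 D | 0.3 | 0.50 | early keratoconus |
| R5 | cct_um | below | 480 µm | 0 (hard) | 1.0 | surgery contraindicated |

These defaults are the package's own operating point assembled from
familiar screening heuristics (elevated Kmax, reduced pachymetry, high
astigmatism, inferior-superior asymmetry, and a hard pachymetry floor for
surgery); they are deliberately config-first — `buildDefaultGraph(rules =
…, prior = …)` or an edited graph file substitutes real institutional
thresholds without code changes. Soft logistic activations were chosen
over hard thresholds as the default because continuous scores are what
ROC analysis needs; s → 0 recovers rule-book behavior exactly (activation
1 strictly past τ, 0.5 at τ). The early-keratoconus prior defaults to
0.05, a screening-population figure, and is likewise configuration.

`loadGraph()` enforces `validateGraph()` (layering, weights, rules,
priors, acyclicity), so any graph that loads is valid; serialization is
canonical JSON (sorted keys, version tag), making saves byte-stable.

## 4. Inference

The posterior combines activated rules by **noisy-OR with the prior as
leak**: P(KC) = 1 − (1 − p0)·∏(1 − wᵢaᵢ). Noisy-OR is the standard
Bayesian-network idiom for independent risk factors; it keeps each edge
weight interpretable as a link probability, reduces to the prior when no
rule fires, is monotone in every activation and weight, and the tests pin
it against brute-force enumeration of the underlying causal model to
1e-12. The normal-cornea diagnosis is scored as the complement 1 − P(KC)
rather than inferred independently — a deliberate binary-screening choice
that avoids unnormalized multi-diagnosis machinery.

Eligibility: contraindicated iff P(KC) ≥ τ_d **or** any hard
(softness-0) parameter→decision rule fired at activation 1. τ_d defaults
to 0.30 — screening favors sensitivity — and is configuration.

Neural-symbolic fusion is a logit-linear pool, logit(p) = (1 −
α)·logit(p_sym) + α·logit(p_neur), with probabilities clamped to
[1e−6, 1 − 1e−6] before the logit for numerical safety. α defaults to
0.30 when an encoder is supplied, but α = 0 (symbolic-only) is the
out-of-box mode: the pipeline is bit-identical with or without a trained
encoder at α = 0, which the tests assert.

A rule is reported as *fired* when its activation is ≥ 0.5, i.e. the
observed value is at or past the threshold; hard decision rules require
activation exactly 1. The `ReasoningTrace` carries the four stages
(parameters → rules → posterior → decision) with unrounded values;
trace JSON uses 17 significant digits so round-trips are bit-exact.

## 5. Map indices and the encoder

The inferior-superior (I-S) asymmetry index is the mean power over the
inferior half of the 2–3 mm mid-peripheral annulus minus the superior
half — the classical keratoconus screening index, chosen as the concrete
"asymmetric curvature" feature. It is invariant to adding a constant to
the map; the map maximum is equivariant. Maps narrower than 6 mm are
rejected. When no map is supplied, the I-S rule is skipped with a notice
rather than failing the whole record.

The encoder is a compact CNN–ViT hybrid: two 3×3 stride-2 convolutions
(8, 16 channels) → 4×4 patch tokens (16 tokens) with a learned positional
embedding → two pre-layer-norm transformer blocks (dim 64, 4 heads, MLP
128) → mean pooling → projection to a unit-norm 64-d embedding. Training
aligns map embeddings with two jointly learned diagnosis-node embeddings
under a **symmetric InfoNCE** loss (map→node cross-entropy over the two
nodes plus node→map cross-entropy over the batch, averaged), temperature
0.1. The optimizer is SGD with momentum 0.9, learning rate 0.05 halved
after 3 stale validation epochs, early stopping after 5, at most 40
epochs, batch 32, stratified 80/20 validation split. Sizes were fixed so
CPU training on 200 maps of 64×64 finishes in well under a minute; the
architecture family, not its scale, is the point. Forward and backward
passes are hand-written in base R (no deep-learning framework is
required) and are verified against central-difference gradients in the
test suite. Validation labels are read only through the early-stopping
loss. Single-threaded seeded training is the tested, bit-reproducible
mode; BLAS-threaded speed is not guaranteed reproducible. The neural
score is the early-keratoconus component of the softmax over cosine
similarities to the two node embeddings.

## 6. Reporting

Reports are pure functions of (trace, catalog, audience, language).
Catalogs are YAML data files; English and Simplified Chinese ship (the
clinical setting implies a zh/en pairing, and the catalog slot accepts
any language). Physician reports render fixed sections — measurements,
evidence, probability, decision, caveats — with every fired rule's
identifier, observed value, threshold and direction; probabilities print
to three decimals, and every formatted number used is embedded in the
JSON appendix next to the full-precision trace. Patient summaries band
the probability (low < 0.1, moderate from 0.1 to τ_d, elevated ≥ τ_d —
the elevated band starts exactly at the decision threshold so patient
wording can never contradict the decision) and are linted against a
maintained jargon blocklist. The external text-generator interface is an
adapter only: it receives the trace JSON and the deterministic report as
grounding, and any failure falls back to the deterministic report with a
notice. No external service is called anywhere in the package or tests.

## 7. Evaluation harness

Folds are seeded shuffles with round-robin assignment, stratified within
class with a carried counter so overall fold sizes differ by at most one.
AUC is the Mann-Whitney rank statistic with half credit for ties (the
all-tied case is exactly 0.5); the tests pin it against exhaustive
positive-negative pair enumeration and against an independent reference
implementation. Bootstrap CIs are percentile 2.5/97.5 over seeded case
resampling of (label, score) pairs (default 1000 replicates; resamples
that lose a class are redrawn). Confusion metrics return NaN sentinels
with warnings on zero denominators, never silent zeros. Cross-validation
reports metrics at τ_d and at the pooled Youden-optimal threshold, per
fold and pooled, with pooled primary; the scoring path receives records
and maps only, and any train/test overlap is a hard error.

## 8. Problem sizes used by the shipped benchmarks

The package's standing benchmarks, chosen once as desk-scale study
conditions: generator calibration on 10,000 marginal-mode eyes (each
parameter's sample mean recovered within 4 standard errors); the
symbolic-only benchmark on 1,000 labeled eyes (kc fraction 0.5, seed 7),
five-fold CV, expected pooled AUC ≥ 0.90; the encoder benchmark on 200
maps (64×64, seed 21) with an 80/20 split, expected held-out AUC ≥ 0.9.
The noisy-OR and AUC oracles run over exhaustive small grids (rule sets
of size ≤ 3; 200 random instances with n ≤ 50).

## 9. Known limitations

- Thresholds, weights and the prior are package defaults, not validated
  clinical parameters; any deployment must substitute institutional
  values through the configuration surface.
- The simulator's idealized morphology means synthetic benchmark
  performance says nothing about performance on real device exports;
  no real-data claim is made anywhere.
- Astigmatism is magnitude-only; meridian-axis information and
  irregularity indices beyond I-S asymmetry are not modeled.
- Whether Kmax derives from anterior axial or total corneal power is
  left opaque: the record treats it as a maximum-keratometry scalar.
- The encoder is deliberately small and trained from scratch; no
  transfer learning, saliency maps or GPU-scale training.
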