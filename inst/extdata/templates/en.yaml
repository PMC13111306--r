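language: en
catalog_version: "1.0"
params:
  k1_D: {label: "Flat keratometry (K1)", unit: "D"}
  k2_D: {label: "Steep keratometry (K2)", unit: "D"}
  kmax_D: {label: "Maximum keratometry (Kmax)", unit: "D"}
  cct_um: {label: "Central corneal thickness", unit: "um"}
  axial_length_mm: {label: "Axial length", unit: "mm"}
  acd_mm: {label: "Anterior chamber depth", unit: "mm"}
  astigmatism_D: {label: "Corneal astigmatism", unit: "D"}
  mean_k_D: {label: "Mean keratometry", unit: "D"}
  astig_kdiff_D: {label: "Keratometric astigmatism (K2-K1)", unit: "D"}
  kmax_excess_D: {label: "Kmax excess over mean K", unit: "D"}
  is_asymmetry_D: {label: "Inferior-superior asymmetry", unit: "D"}
  max_power_D: {label: "Maximum map power", unit: "D"}
direction_words:
  above: "above"
  below: "below"
physician:
  title: "Corneal topography interpretation — physician report — eye {eye_id}"
  measurements_header: "Measured biometric parameters"
  measurement_line: "- {label}: {value} {unit}"
  evidence_header: "Diagnostic evidence"
  rule_line: "- [{rule_id}] {label} = {value} {unit}, {direction} the clinical threshold of {threshold} {unit} (evidence strength {activation})"
  no_rules: "No diagnostic criteria were met."
  probability_header: "Disease probability"
  probability_line: "Estimated probability of early keratoconus: {p} (screening prior {prior})."
  decision_header: "Refractive surgery eligibility"
  decision_candidate: "The eye is a candidate for refractive surgery at the decision threshold {tau_d}."
  decision_contraindicated: "Refractive surgery is contraindicated at the decision threshold {tau_d}."
  trigger_line: "- Hard contraindication [{rule_id}]: {label} = {value} {unit}, {direction} {threshold} {unit}."
  caveats_header: "Caveats"
  caveats: "This report is generated from biometric measurements and an encoded clinical rule base; it supports but does not replace clinical judgment. Borderline values warrant corneal tomography and follow-up."
patient:
  title: "Your corneal examination summary — eye {eye_id}"
  findings_header: "What we measured"
  findings: "We measured the shape and thickness of the front surface of your eye (the cornea) several times to get a stable picture."
  risk_header: "What the results suggest"
  band_low: "The measurements look reassuring: the likelihood of an early corneal shape condition (keratoconus) is low."
  band_moderate: "Some measurements are borderline: there is a moderate chance of an early corneal shape condition (keratoconus), and a follow-up examination is sensible."
  band_elevated: "Several measurements point to an elevated chance of an early corneal shape condition (keratoconus). Your doctor will discuss further testing with you."
  decision_header: "About laser vision correction"
  decision_candidate: "Based on these results, laser vision correction remains an option you can discuss with your doctor."
  decision_contraindicated: "Based on these results, laser vision correction is not advisable at this time; your doctor will explain the alternatives."
  caveats_header: "Good to know"
  caveats: "This summary was prepared automatically from your measurements. Your eye doctor makes the final assessment together with you."
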