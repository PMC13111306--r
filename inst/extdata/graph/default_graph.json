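{
  "version": "1.0",
  "nodes": [
    {"category": "parameter", "label": "Flat keratometry (K1)", "label_en": "Flat keratometry (K1)", "label_zh": "平坦角膜曲率 (K1)", "node_id": "K1"},
    {"category": "parameter", "label": "Steep keratometry (K2)", "label_en": "Steep keratometry (K2)", "label_zh": "陡峭角膜曲率 (K2)", "node_id": "K2"},
    {"category": "parameter", "label": "Maximum keratometry (Kmax)", "label_en": "Maximum keratometry (Kmax)", "label_zh": "最大角膜曲率 (Kmax)", "node_id": "Kmax"},
    {"category": "parameter", "label": "Central corneal thickness", "label_en": "Central corneal thickness", "label_zh": "中央角膜厚度", "node_id": "CCT"},
    {"category": "parameter", "label": "Axial length", "label_en": "Axial length", "label_zh": "眼轴长度", "node_id": "AL"},
    {"category": "parameter", "label": "Anterior chamber depth", "label_en": "Anterior chamber depth", "label_zh": "前房深度", "node_id": "ACD"},
    {"category": "parameter", "label": "Corneal astigmatism", "label_en": "Corneal astigmatism", "label_zh": "角膜散光", "node_id": "astigmatism"},
    {"category": "parameter", "label": "Inferior-superior asymmetry", "label_en": "Inferior-superior asymmetry", "label_zh": "下方-上方不对称指数", "node_id": "IS_asymmetry"},
    {"category": "diagnosis", "label": "Early keratoconus", "label_en": "Early keratoconus", "label_zh": "早期圆锥角膜", "node_id": "early_keratoconus"},
    {"category": "diagnosis", "label": "Normal cornea", "label_en": "Normal cornea", "label_zh": "正常角膜", "node_id": "normal_cornea"},
    {"category": "decision", "label": "Refractive surgery candidate", "label_en": "Refractive surgery candidate", "label_zh": "适合屈光手术", "node_id": "surgery_candidate"},
    {"category": "decision", "label": "Refractive surgery contraindicated", "label_en": "Refractive surgery contraindicated", "label_zh": "屈光手术禁忌", "node_id": "surgery_contraindicated"}
  ],
  "edges": [
    {"rule": {"direction": "above", "feature": "kmax_D", "rule_id": "R1", "softness": 0.5, "threshold": 47.0}, "source": "Kmax", "target": "early_keratoconus", "weight": 0.60},
    {"rule": {"direction": "below", "feature": "cct_um", "rule_id": "R2", "softness": 10.0, "threshold": 500.0}, "source": "CCT", "target": "early_keratoconus", "weight": 0.45},
    {"rule": {"direction": "above", "feature": "astig_kdiff_D", "rule_id": "R3", "softness": 0.3, "threshold": 2.0}, "source": "astigmatism", "target": "early_keratoconus", "weight": 0.25},
    {"rule": {"direction": "above", "feature": "is_asymmetry_D", "rule_id": "R4", "softness": 0.3, "threshold": 1.4}, "source": "IS_asymmetry", "target": "early_keratoconus", "weight": 0.50},
    {"rule": {"direction": "below", "feature": "cct_um", "rule_id": "R5", "softness": 0.0, "threshold": 480.0}, "source": "CCT", "target": "surgery_contraindicated", "weight": 1.0},
    {"rule": null, "source": "early_keratoconus", "target": "surgery_contraindicated", "weight": 0.9},
    {"rule": null, "source": "normal_cornea", "target": "surgery_candidate", "weight": 0.9}
  ],
  "priors": {
    "early_keratoconus": 0.05,
    "normal_cornea": 0.95
  }
}
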