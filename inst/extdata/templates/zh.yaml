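language: zh
catalog_version: "1.0"
params:
  k1_D: {label: "平坦角膜曲率 (K1)", unit: "D"}
  k2_D: {label: "陡峭角膜曲率 (K2)", unit: "D"}
  kmax_D: {label: "最大角膜曲率 (Kmax)", unit: "D"}
  cct_um: {label: "中央角膜厚度", unit: "μm"}
  axial_length_mm: {label: "眼轴长度", unit: "mm"}
  acd_mm: {label: "前房深度", unit: "mm"}
  astigmatism_D: {label: "角膜散光", unit: "D"}
  mean_k_D: {label: "平均角膜曲率", unit: "D"}
  astig_kdiff_D: {label: "角膜散光差值 (K2-K1)", unit: "D"}
  kmax_excess_D: {label: "Kmax 超出平均曲率", unit: "D"}
  is_asymmetry_D: {label: "下方-上方不对称指数", unit: "D"}
  max_power_D: {label: "地形图最大屈光力", unit: "D"}
direction_words:
  above: "高于"
  below: "低于"
physician:
  title: "角膜地形图判读——医师报告——眼 {eye_id}"
  measurements_header: "生物测量参数"
  measurement_line: "- {label}：{value} {unit}"
  evidence_header: "诊断证据"
  rule_line: "- [{rule_id}] {label} = {value} {unit}，{direction}临床阈值 {threshold} {unit}（证据强度 {activation}）"
  no_rules: "未满足任何诊断标准。"
  probability_header: "疾病概率"
  probability_line: "早期圆锥角膜的估计概率：{p}（筛查先验 {prior}）。"
  decision_header: "屈光手术适应性"
  decision_candidate: "在决策阈值 {tau_d} 下，该眼可作为屈光手术候选。"
  decision_contraindicated: "在决策阈值 {tau_d} 下，屈光手术为禁忌。"
  trigger_line: "- 硬性禁忌 [{rule_id}]：{label} = {value} {unit}，{direction} {threshold} {unit}。"
  caveats_header: "注意事项"
  caveats: "本报告由生物测量数据与编码的临床规则库自动生成，仅辅助而不替代临床判断。临界值建议行角膜断层扫描并随访。"
patient:
  title: "您的角膜检查小结——眼 {eye_id}"
  findings_header: "我们测量了什么"
  findings: "我们对您眼睛前表面（角膜）的形态和厚度进行了多次测量，以获得稳定的结果。"
  risk_header: "结果提示"
  band_low: "测量结果令人放心：出现早期角膜形态异常（圆锥角膜）的可能性较低。"
  band_moderate: "部分测量值处于临界范围：出现早期角膜形态异常（圆锥角膜）的可能性为中等，建议复查。"
  band_elevated: "多项测量值提示出现早期角膜形态异常（圆锥角膜）的可能性偏高。医生会与您讨论进一步检查。"
  decision_header: "关于激光视力矫正"
  decision_candidate: "根据这些结果，您仍可与医生讨论激光视力矫正的可行性。"
  decision_contraindicated: "根据这些结果，目前不建议进行激光视力矫正；医生会向您说明其他选择。"
  caveats_header: "温馨提示"
  caveats: "本小结由您的测量数据自动生成，最终评估由您的眼科医生与您共同完成。"
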