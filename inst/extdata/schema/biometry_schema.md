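# Per-eye biometry record schema (version 1.0)

One record describes the repeated raw scans of a single eye acquired in one
examination session. Units are fixed: curvature/power in diopters (D),
corneal thickness in micrometers (um), axial length and anterior chamber
depth in millimeters (mm). Missing measurements are represented explicitly
(JSON `null` / empty CSV cell), never as zero, and are never imputed —
incomplete records are excluded by quality control.

## JSON dialect (`records.json`)

Top-level: a list of eye objects.

```json
[
  {
    "eye_id": "EYE00001",
    "laterality": "OD",
    "scans": [
      {"order": 1, "k1_D": 43.1, "k2_D": 44.2, "kmax_D": 46.0,
       "cct_um": 533, "axial_length_mm": 24.2, "acd_mm": 3.2},
      {"order": 2, "...": "..."},
      {"order": 3, "...": "..."}
    ]
  }
]
```

- `eye_id` (string, required): opaque unique identifier; one record per eye.
- `laterality` (string, optional): `OD` (right) or `OS` (left).
- `scans` (list, required, length >= 1; 3 expected by default): raw
  measurement tuples. `order` is the acquisition sequence number and must be
  unique within the eye.
- Unknown fields at any level are preserved as opaque metadata.

## CSV dialect (`records.csv`)

UTF-8, header required, `.` decimal separator, one row per scan:

```
eye_id,laterality,order,k1_D,k2_D,kmax_D,cct_um,axial_length_mm,acd_mm
EYE00001,OD,1,43.1,44.2,46.0,533,24.2,3.2
```

Extra columns are preserved as metadata. Rows sharing an `eye_id` form that
eye's scan set; duplicate `(eye_id, order)` pairs are rejected.

## Field semantics

| field | unit | meaning |
|---|---|---|
| `k1_D` | D | flat-meridian keratometry |
| `k2_D` | D | steep-meridian keratometry (`k2_D >= k1_D` after aggregation) |
| `kmax_D` | D | maximum keratometry over the mapped surface |
| `cct_um` | um | central corneal thickness |
| `axial_length_mm` | mm | axial length |
| `acd_mm` | mm | anterior chamber depth |

The aggregated record additionally carries `astigmatism_D` (D), the median
per-scan `k2_D - k1_D` (magnitude convention; no meridian axis is modeled).

## Companion files written by the simulator

- `labels.csv`: `eye_id,label` with `label` in `normal`/`early_kc`; kept
  separate so the inference path cannot read class labels.
- `maps/<eye_id>.csv`: axial curvature map grid in D; first line is a
  comment header `# curvature map eye_id=... pixel_mm=... background=...`,
  remaining lines the square matrix (row 1 = superior edge, +x temporal for
  a right eye). Optional `maps/<eye_id>.png` uses a fixed 38-52 D color
  scale.
- `manifest.json`: every artifact with its MD5 checksum.
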