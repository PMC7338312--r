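{
 "description": "Synthetic digital phantom in the style of the IBSI reference object: a small integer-valued grid with excluded voxels for validating texture-feature implementations. This is a stand-in constructed for this package, not the IBSI consortium phantom; the reference values below were computed with an independent brute-force enumerator.",
 "dims": [
  5,
  4,
  4
 ],
 "spacing_mm": [
  2.0,
  2.0,
  2.0
 ],
 "n_bins": 6,
 "values_column_major": [
  1.0,
  1.0,
  2.0,
  2.0,
  1.0,
  1.0,
  6.0,
  6.0,
  1.0,
  null,
  3.0,
  6.0,
  4.0,
  4.0,
  4.0,
  2.0,
  1.0,
  5.0,
  1.0,
  1.0,
  1.0,
  6.0,
  1.0,
  6.0,
  5.0,
  4.0,
  5.0,
  4.0,
  null,
  1.0,
  1.0,
  4.0,
  2.0,
  null,
  1.0,
  6.0,
  null,
  5.0,
  1.0,
  1.0,
  4.0,
  null,
  4.0,
  1.0,
  4.0,
  null,
  1.0,
  1.0,
  6.0,
  5.0,
  1.0,
  2.0,
  1.0,
  1.0,
  1.0,
  1.0,
  6.0,
  2.0,
  4.0,
  2.0,
  1.0,
  1.0,
  1.0,
  4.0,
  3.0,
  3.0,
  2.0,
  1.0,
  4.0,
  3.0,
  6.0,
  1.0,
  6.0,
  4.0,
  1.0,
  6.0,
  4.0,
  3.0,
  6.0,
  5.0
 ],
 "reference_values": {
  "suv_max": 6.0,
  "matv": 0.592,
  "intensity_entropy": 1.603382117627752,
  "glcm_asm": 0.07016591088086678,
  "glcm_sum_entropy": 2.1219574773602976,
  "rlnu": 51.599828404949,
  "hglre": 12.854443383072486,
  "zsnu": 5.25,
  "hglze": 13.8125
 },
 "tolerance_relative": 1e-06
}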