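label_weights:
  A: 4.0
  B: 3.0
  C: 2.0
  D: 1.0
internal_quarter_multiplier: 1.5
three_quarter_internal_multiplier: 1.25
scatter_surcharge: 4.0
at_core_bonus_full: 1.0
at_core_bonus_noncanonical: 2.0
spacer_penalties:
- 0.0
- 2.0
- 3.0
- 8.0
- 8.0
- 8.0
- 8.0
- 8.0
- 8.0
- 8.0
- 8.0
- 8.0
- 8.0
- 8.0
long_spacer_grade_cap: 2
grade_thresholds:
  '5': 0.0
  '4': 2.0
  '3': 5.0
  '2': 9.0
  '1': 14.0
class_ceilings:
  full: 5
  3Q: 3
  half: 2
no_grade_min_mismatches: 4
no_grade_min_quarters: 3
grade5_max_mismatches: 2
drop_half_sites_with_core_mismatch: yes
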