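# Illustrative 16-component adherence-index specification.
#
# Component names follow the dietary-guideline set the 0-160 index
# summarises; every cutoff below is a PLACEHOLDER chosen for demonstration
# and testing of the scoring engine. The published guideline cut-off
# constants are defined elsewhere and must be supplied by the analyst for a
# real study. Units: g/day unless noted.
components:
  - name: whole_grains          # range: minimum and maximum intake frequency
    kind: range
    full_score_cutoff: [90.0, 250.0]
    zero_score_cutoff: [0.0, 400.0]
    cap_rule: {percentile: 100, target: zero}
  - name: fruits
    kind: adequacy
    full_score_cutoff: 200.0
    zero_score_cutoff: 0.0
  - name: vegetables
    kind: adequacy
    full_score_cutoff: 250.0
    zero_score_cutoff: 0.0
  - name: legumes
    kind: adequacy
    full_score_cutoff: 25.0
    zero_score_cutoff: 0.0
  - name: low_fat_dairy
    kind: adequacy
    full_score_cutoff: 150.0
    zero_score_cutoff: 0.0
  - name: low_fat_cheese
    kind: adequacy
    full_score_cutoff: 30.0
    zero_score_cutoff: 0.0
  - name: fish
    kind: adequacy
    full_score_cutoff: 40.0
    zero_score_cutoff: 0.0
  - name: low_fat_meat_poultry
    kind: adequacy
    full_score_cutoff: 60.0
    zero_score_cutoff: 0.0
    cap_rule: {percentile: 100, target: full}
  - name: nuts
    kind: adequacy
    full_score_cutoff: 15.0
    zero_score_cutoff: 0.0
  - name: olive_oil
    kind: adequacy
    full_score_cutoff: 20.0
    zero_score_cutoff: 0.0
  - name: fluids                # ml/day
    kind: adequacy
    full_score_cutoff: 1500.0
    zero_score_cutoff: 0.0
  - name: vitamin_d_supplement  # ug/day
    kind: adequacy
    full_score_cutoff: 10.0
    zero_score_cutoff: 0.0
  - name: eggs                  # items/week band
    kind: range
    full_score_cutoff: [2.0, 4.0]
    zero_score_cutoff: [0.0, 8.0]
  - name: alcohol
    kind: limit
    full_score_cutoff: 5.0
    zero_score_cutoff: 30.0
  - name: sodium                # mg/day
    kind: limit
    full_score_cutoff: 1500.0
    zero_score_cutoff: 3000.0
    cap_rule: {percentile: 85, target: zero}
  - name: sweets
    kind: limit
    full_score_cutoff: 10.0
    zero_score_cutoff: 80.0
    cap_rule: {percentile: 85, target: zero}
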