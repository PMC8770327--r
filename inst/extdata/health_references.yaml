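# Health-based guidance values (HBGVs) and benchmark-dose reference points
# used for risk characterization. Weekly and monthly tolerable intakes are
# recalculated to a daily basis before comparison (week / 7, month / 30).
# `concern` states which tail of the intake distribution the reference
# guards against: "deficit" (intake below the value is the concern) or
# "excess". BMDL entries are reference points for margin-of-exposure
# evaluation of non-threshold effects, not tolerable levels.
version: 1
references:
  - substance: iodine
    authority: EFSA
    ref_type: AI
    value: 150
    period: day
    unit: ug/day
    concern: deficit
    critical_effect: goiter prevalence at insufficient intake
  - substance: iodine
    authority: EFSA
    ref_type: UL
    value: 600
    period: day
    unit: ug/day
    concern: excess
    critical_effect: biochemical changes in thyroid-stimulating hormone
  - substance: sodium
    authority: EFSA
    ref_type: safe_adequate
    value: 2000
    period: day
    unit: mg/day
    concern: excess
    critical_effect: elevated blood pressure and cardiovascular disease
  - substance: cadmium
    authority: EFSA
    ref_type: PTWI
    value: 2.5
    period: week
    unit: ug/kg bw/week
    concern: excess
    critical_effect: kidney proximal tubular cell toxicity
  - substance: cadmium
    authority: JECFA
    ref_type: PTMI
    value: 25
    period: month
    unit: ug/kg bw/month
    concern: excess
    critical_effect: kidney toxicity
  - substance: mercury
    species: methyl
    authority: EFSA
    ref_type: PTWI
    value: 1.3
    period: week
    unit: ug/kg bw/week
    concern: excess
    critical_effect: neurodevelopmental toxicity
  - substance: mercury
    species: inorganic
    authority: EFSA/JECFA
    ref_type: PTWI
    value: 4
    period: week
    unit: ug/kg bw/week
    concern: excess
    critical_effect: nephrotoxicity
  - substance: i_arsenic
    authority: EFSA
    ref_type: BMDL_range
    label: BMDL01
    value: 0.3
    value_upper: 8
    period: day
    unit: ug/kg bw/day
    concern: excess
    critical_effect: cancer of the lung, skin and bladder; skin lesions
  - substance: i_arsenic
    authority: JECFA
    ref_type: BMDL_single
    label: BMDL0.5
    value: 3.0
    period: day
    unit: ug/kg bw/day
    concern: excess
    critical_effect: lung cancer (0.5% increased incidence)
  - substance: lead
    authority: EFSA
    ref_type: BMDL_single
    label: BMDL01
    value: 1.5
    period: day
    unit: ug/kg bw/day
    concern: excess
    critical_effect: systolic blood pressure (1% increase)
  - substance: lead
    authority: EFSA
    ref_type: BMDL_single
    label: BMDL10
    value: 0.63
    period: day
    unit: ug/kg bw/day
    concern: excess
    critical_effect: chronic kidney disease (10% increased incidence)
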