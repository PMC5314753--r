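# Default pipeline configuration.
# Population total is anchored so that a 12.9% age-standardised PTSD
# prevalence yields 2.2 million prevalent cases.
seed: 20150101
population:
  total: 17054263.57
  reference_year: 2015
prevalence:
  ptsd:        {point: 0.129, lower: 0.069, upper: 0.229}
  depression:  {point: 0.076, lower: 0.051, upper: 0.109}
  comorbid_rho: 0.5
severity:
  depression:
    classes:
      - {class: asymptomatic, proportion: 0.145, dw: 0.000}
      - {class: mild,         proportion: 0.575, dw: 0.159, dw_lower: 0.107, dw_upper: 0.223}
      - {class: moderate,     proportion: 0.197, dw: 0.406, dw_lower: 0.276, dw_upper: 0.551}
      - {class: severe,       proportion: 0.083, dw: 0.655, dw_lower: 0.469, dw_upper: 0.816}
  anxiety:
    classes:
      - {class: asymptomatic, proportion: 0.102, dw: 0.000}
      - {class: mild,         proportion: 0.598, dw: 0.030, dw_lower: 0.018, dw_upper: 0.046}
      - {class: moderate,     proportion: 0.148, dw: 0.133, dw_lower: 0.091, dw_upper: 0.186}
      - {class: severe,       proportion: 0.152, dw: 0.523, dw_lower: 0.362, dw_upper: 0.677}
services:
  baseline_coverage: 0.01
benefit:
  discount_rate: 0.0
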