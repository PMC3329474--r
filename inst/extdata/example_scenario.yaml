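# Minimal synthetic scenario: three EU detectors, three non-EU transgressors,
# mycotoxin-dominated mixture.
countries:
  - {country: DEU, detect_rate: 2.0, transgress_rate: 0.4}
  - {country: ITA, detect_rate: 1.5, transgress_rate: 0.3}
  - {country: ESP, detect_rate: 1.0, transgress_rate: 0.5}
  - {country: IRN, detect_rate: 0.0, transgress_rate: 2.5}
  - {country: CHN, detect_rate: 0.0, transgress_rate: 1.5}
  - {country: BRA, detect_rate: 0.0, transgress_rate: 1.0}
date_range: ["2005-01-01", "2008-08-31"]
n_notifications: 1000
uncategorized_prob: 0.396
border_rejection_prob: 0.25
seed: 1
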