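# Example run configuration for the effectmodel simulation commands.
# Population: a synthetic 200-subject cohort (illustrative descriptor
# distributions, not calibrated to any real population).
seed: 1
population:
  size: 200
  seed: 1
  descriptors:
    - {name: x_absorption,    distribution: lognormal, location: 0,  scale: 0.25}
    - {name: x_age,           distribution: normal,    location: 60, scale: 10, bounds: [30, 90]}
    - {name: x_emax_genes,    distribution: lognormal, location: 0,  scale: 0.30}
    - {name: x_binding_genes, distribution: lognormal, location: 0,  scale: 0.30}
    - {name: x_transduction,  distribution: lognormal, location: 0,  scale: 0.30}
    - {name: x_sympathetic,   distribution: lognormal, location: 0,  scale: 0.40}
    - {name: y_biomarker,     distribution: normal,    location: 0,  scale: 1}
    - {name: y_risk_factor,   distribution: normal,    location: 0,  scale: 1}
disease:
  beta0: -2
  beta_biomarker: 0.8
  beta_risk_factor: 0.6
therapies:
  - label: drugA
    dosing_interval: 24   # hours
    followup: 1           # years
    harm: 0
    pkpd:
      dose: 100           # mg
      bioavailability_f0: 0.8
      ka: 1.0             # 1/h
      ke0: 0.1            # 1/h
      volume: 50          # L
      gamma: 1.5
      ec50_0: 0.5         # mg/L
      smax_0: 2
      transduction_gain: 1
      feedback_h: 0.2
  - label: drugB          # same drug at half dose with a small constant harm
    dosing_interval: 24
    followup: 1
    harm: 0.01
    pkpd:
      dose: 50
      bioavailability_f0: 0.8
      ka: 1.0
      ke0: 0.1
      volume: 50
      gamma: 1.5
      ec50_0: 0.5
      smax_0: 2
      transduction_gain: 1
      feedback_h: 0.2
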