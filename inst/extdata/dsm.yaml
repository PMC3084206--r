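# Bundled sporulation-medium scenario: three sequentially exhausted
# nutrients give two diauxic growth-rate pauses and a final arrest at the
# entry to stationary phase; the polymerase-limited spo0A-like promoter
# bursts at each pause and a scripted stationary program adds the three
# post-arrest transcription waves (the last the strongest, so the
# growth-phase peaks sit at 50-75% of the final maximum).
name: dsm
x0: 0.05
duration: 7.0
sampling_interval: 0.025
noise_cv: 0.02
od_background: 0.04
medium:
  induction_rate: 6.0
  decay_rate: 0.0
  switch_conc: 0.002
  repression_order: [glucose, overflow1, overflow2]
  substrates:
    - {name: glucose,   conc: 0.60, mu_max: 1.2, K_s: 0.02, yield: 0.5}
    - {name: overflow1, conc: 0.50, mu_max: 0.8, K_s: 0.02, yield: 0.5}
    - {name: overflow2, conc: 0.55, mu_max: 0.55, K_s: 0.02, yield: 0.5}
rnap: {f_max: 0.9, K_mu: 0.2, R_total: 1.0}
reporter: {half_life: 0.1, light_coeff: 1000.0, maturation_delay: 0.0}
spo0a: {source: spo0A, gamma_P: 0.7, k_phos: 0.4, k_deph: 1.0, kappa: 1.0}
promoters:
  - {name: spo0A,  class: constitutive, strength: 100.0, K_R: 0.3,
     initiating_nucleotide: A}
  - {name: rrnB,   class: rrn_like, strength: 80.0,
     initiating_nucleotide: G, intp_K: 0.3}
  - {name: abrB,   class: repressed, strength: 60.0, K_R: 0.3,
     initiating_nucleotide: A, regulator_K: 30.0, hill_n: 2}
  - {name: spoIIG, class: activated, strength: 1000.0,
     initiating_nucleotide: A, regulator_K: 45.0, hill_n: 4}
  - {name: comK,   class: constitutive, strength: 20.0, K_R: 0.3,
     initiating_nucleotide: A}
gtp_dip_schedule:
  - {start: 1.65, end: 2.05, depth: 0.5}
stationary_program:
  - {time: 3.90, step: -20.0, promoter: spo0A}
  - {time: 4.15, step: 26.0, promoter: spo0A}
  - {time: 4.45, step: -24.0, promoter: spo0A}
  - {time: 4.70, step: 20.0, promoter: spo0A}
  - {time: 5.50, step: 25.0, promoter: spo0A}
  - {time: 6.50, step: -25.0, promoter: spo0A}
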