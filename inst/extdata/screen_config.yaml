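# Synthetic 25-strain deletion screen: a wild-type reference, eight
# long-lived deletions (full-distribution mean ~1.4x wild-type) and
# sixteen deletions with wild-type lifespan. 200 cells per strain pooled
# from two replicates, 72-h experiment.
design:
  n_cells: 200
  n_replicates: 2
  duration_h: 72
  base_cycle_min: 90
  cycle_cv: 0.2
  elongation_factor: 1
  elongation_window: 5
  seed: 20260924
wildtype: WT
strains:
  - {strain: WT,     r: 0.0392, alpha: 3.6}
  - {strain: pmt1,   r: 0.0280, alpha: 3.6}
  - {strain: pmt5,   r: 0.0280, alpha: 3.6}
  - {strain: alg3,   r: 0.0280, alpha: 3.6}
  - {strain: ost3,   r: 0.0280, alpha: 3.6}
  - {strain: rpl12a, r: 0.0280, alpha: 3.6}
  - {strain: rpl31a, r: 0.0280, alpha: 3.6}
  - {strain: rps27b, r: 0.0280, alpha: 3.6}
  - {strain: rpp2b,  r: 0.0280, alpha: 3.6}
  - {strain: yak1,   r: 0.0392, alpha: 3.6}
  - {strain: fob1,   r: 0.0392, alpha: 3.6}
  - {strain: gpa2,   r: 0.0392, alpha: 3.6}
  - {strain: tor1,   r: 0.0392, alpha: 3.6}
  - {strain: sch9,   r: 0.0392, alpha: 3.6}
  - {strain: hxk2,   r: 0.0392, alpha: 3.6}
  - {strain: cyr1,   r: 0.0392, alpha: 3.6}
  - {strain: rim15,  r: 0.0392, alpha: 3.6}
  - {strain: gis1,   r: 0.0392, alpha: 3.6}
  - {strain: msn2,   r: 0.0392, alpha: 3.6}
  - {strain: msn4,   r: 0.0392, alpha: 3.6}
  - {strain: snf1,   r: 0.0392, alpha: 3.6}
  - {strain: adr1,   r: 0.0392, alpha: 3.6}
  - {strain: cat8,   r: 0.0392, alpha: 3.6}
  - {strain: sip4,   r: 0.0392, alpha: 3.6}
  - {strain: mig1,   r: 0.0392, alpha: 3.6}
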