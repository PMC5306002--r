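# Composite hierarchical-divergence model for a three-region island
# system: deep northern isolation, a center--south split, sequential
# central splits and one southern split, each preceded by a 20-fold
# bottleneck (duration db) with recovery to the stable size.
scenarios:
  composite:
    pops: [north, bp, ses, pf, south, lnr]
    Ne: {north: Ne, bp: Ne, ses: Ne, pf: Ne, south: Ne, lnr: Ne}
    events:
      - {type: size,  time: t_pf_b,    pop: pf,    Ne: Nb}
      - {type: size,  time: t_lnr_b,   pop: lnr,   Ne: Nb}
      - {type: merge, time: t_pf,      from: pf,   to: ses}
      - {type: merge, time: t_lnr,     from: lnr,  to: south}
      - {type: size,  time: t_ses_b,   pop: ses,   Ne: Nb}
      - {type: merge, time: t_ses,     from: ses,  to: bp}
      - {type: size,  time: t_cs_b,    pop: south, Ne: Nb}
      - {type: size,  time: t_cs_b,    pop: bp,    Ne: Nb}
      - {type: merge, time: t_cs,      from: south, to: bp}
      - {type: size,  time: t_cs,      pop: bp,    Ne: Ne}
      - {type: size,  time: t_north_b, pop: north, Ne: Nb}
      - {type: size,  time: t_north_b, pop: bp,    Ne: Nb}
      - {type: merge, time: t_north,   from: north, to: bp}
      - {type: size,  time: t_north,   pop: bp,    Ne: Ne}
    conditions:
      - "t_north > t_cs"
      - "t_cs > t_ses"
      - "t_ses > t_pf"
      - "t_north_b < t_north"
      - "t_north_b > t_cs"
      - "t_cs_b < t_cs"
      - "t_ses_b < t_ses"
      - "t_pf_b < t_pf"
      - "t_lnr_b < t_lnr"
priors:
  Ne:       {dist: logunif, min: 1000.0,    max: 10000.0}
  Nb:       {dist: logunif, min: 50.0,      max: 1000.0}
  t_north:  {dist: logunif, min: 1000000.0, max: 10000000.0}
  t_north_b: {dist: logunif, min: 500000.0, max: 9000000.0}
  t_cs:     {dist: logunif, min: 10000.0,   max: 20000.0}
  t_cs_b:   {dist: logunif, min: 8000.0,    max: 19000.0}
  t_ses:    {dist: logunif, min: 4000.0,    max: 8000.0}
  t_ses_b:  {dist: logunif, min: 3000.0,    max: 7000.0}
  t_pf:     {dist: logunif, min: 2000.0,    max: 4000.0}
  t_pf_b:   {dist: logunif, min: 1000.0,    max: 3500.0}
  t_lnr:    {dist: logunif, min: 2000.0,    max: 4000.0}
  t_lnr_b:  {dist: logunif, min: 1000.0,    max: 3500.0}
  mu_seq:   {dist: logunif, min: 1.0e-8,    max: 1.0e-6}
config:
  marker: seq
  samples: {north: 25, bp: 9, ses: 9, pf: 8, south: 34, lnr: 11}
  length: 491
  prop_invariant: 0.61
  gamma_shape: 0.78
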