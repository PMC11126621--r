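# Optimised design: identical to the initial design except d1 (10 -> 20 cm)
# and dd (33 -> 100 cm).  The tracked defect mode lies near 1800 Hz; the
# operating window below covers it at every CO2 enrichment in 0..100 units.
geometry:
  units: cm
  d1: 20.0
  d2: 6.0
  d3: 6.0
  dd: 100.0
  S1: 1.0
  S2: 0.9
  S3: 0.9
  Sd: 1.0
  n_cells: 10
mixture:
  deb_enrichment: 0
mixture_high:
  deb_enrichment: 100
scan:
  f_start: 0.1
  f_stop: 3000.0
  step: 0.05
peak:
  f_window: [1700.0, 1910.0]
  threshold: 1.0
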