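# Starting design of the breath-CO2 phononic-crystal sensor.
# Lengths in cm, cross-sections in cm^2; the defect mode sits in the third
# band gap.
geometry:
  units: cm
  d1: 10.0
  d2: 6.0
  d3: 6.0
  dd: 33.0
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
  gap_index: 3
  threshold: 1.0
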