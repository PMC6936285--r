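seed: 1
n_beds: 13
bed_spacing_m: 3.5
bed_ids:
- B1
- B2
- B3
- B4
- B5
- B6
- B7
- B8
- B9
- B10
- B11
- B12
- B13
species:
- name: Pseudohastitidae sp. A
  log_mu: 2.890371757896165
  log_sigma: 0.12
  beta_temp: 0.17
  juvenile_offset: -0.6
  juvenile_fraction: 0.35
  occupancy:
  - no
  - yes
  - yes
  - yes
  - yes
  - yes
  - yes
  - yes
  - yes
  - yes
  - no
  - no
  - no
  lambda_per_m2: 30.0
  elongation: 6.0
  compression: 0.95
- name: Passaloteuthidae sp. B
  log_mu: 3.091042453358316
  log_sigma: 0.12
  beta_temp: 0.07
  juvenile_offset: -0.6
  juvenile_fraction: 0.35
  occupancy:
  - yes
  - yes
  - yes
  - yes
  - yes
  - yes
  - yes
  - yes
  - yes
  - yes
  - no
  - no
  - no
  lambda_per_m2: 12.0
  elongation: 4.0
  compression: 1.0
- name: Hastitidae sp. C
  log_mu: 2.484906649788
  log_sigma: 0.12
  beta_temp: -0.08
  juvenile_offset: -0.6
  juvenile_fraction: 0.35
  occupancy:
  - yes
  - yes
  - yes
  - yes
  - yes
  - yes
  - no
  - no
  - no
  - no
  - no
  - no
  - no
  lambda_per_m2: 5.0
  elongation: 5.0
  compression: 0.9
- name: Passaloteuthidae sp. D
  log_mu: 3.218875824868201
  log_sigma: 0.12
  beta_temp: 0.0
  juvenile_offset: -0.6
  juvenile_fraction: 0.35
  occupancy:
  - yes
  - yes
  - yes
  - yes
  - yes
  - no
  - no
  - no
  - no
  - no
  - no
  - no
  - no
  lambda_per_m2: 1.0
  elongation: 4.0
  compression: 1.0
- name: Parapassaloteuthis-like sp. E
  log_mu: 2.639057329615258
  log_sigma: 0.12
  beta_temp: 0.0
  juvenile_offset: -0.6
  juvenile_fraction: 0.35
  occupancy:
  - yes
  - yes
  - yes
  - yes
  - yes
  - no
  - no
  - no
  - no
  - no
  - no
  - no
  - no
  lambda_per_m2: 1.0
  elongation: 4.5
  compression: 0.95
- name: Bairstowius-like sp. F
  log_mu: 3.258096538021482
  log_sigma: 0.12
  beta_temp: 0.0
  juvenile_offset: -0.6
  juvenile_fraction: 0.35
  occupancy:
  - yes
  - yes
  - no
  - no
  - no
  - no
  - no
  - no
  - no
  - no
  - no
  - no
  - no
  lambda_per_m2: 18.0
  elongation: 7.0
  compression: 0.9
- name: Acrocoelites-like sp. G
  log_mu: 2.995732273553991
  log_sigma: 0.12
  beta_temp: 0.0
  juvenile_offset: -0.6
  juvenile_fraction: 0.35
  occupancy:
  - no
  - no
  - no
  - no
  - no
  - no
  - no
  - no
  - no
  - no
  - no
  - no
  - yes
  lambda_per_m2: 2.0
  elongation: 5.0
  compression: 0.95
proxies:
  d18O:
    mean:
    - -1.0
    - -1.0
    - -1.0
    - -1.0
    - -2.0
    - -2.0
    - -1.4
    - -1.4
    - -1.4
    - -1.6
    - -2.4
    - -2.4
    - -2.2
    phi: 0.5
    innovation_sd: 0.05
  d13C:
    mean:
    - 1.5
    - 1.5
    - 1.4
    - 1.4
    - 1.2
    - 1.3
    - 1.5
    - 1.6
    - 1.6
    - 0.5
    - -0.5
    - -0.5
    - 0.8
    phi: 0.4
    innovation_sd: 0.1
  hg_toc:
    mean:
    - 0.02
    - 0.02
    - 0.02
    - 0.05
    - 0.15
    - 0.08
    - 0.03
    - 0.02
    - 0.02
    - 0.12
    - 0.2
    - 0.2
    - 0.05
    phi: 0.3
    innovation_sd: 0.01
lithology_sequence:
- marl
- marly_limestone
- limestone
- marl
- marly_limestone
- limestone
- marl
- marly_limestone
- limestone
- marl
- limestone
- limestone
- marly_limestone
zones:
- Emaciatum
- Emaciatum
- Emaciatum
- Emaciatum
- Polymorphum
- Polymorphum
- Polymorphum
- Polymorphum
- Polymorphum
- Levisoni
- Levisoni
- Levisoni
- Levisoni
n_quadrats_per_bed:
- 2.0
- 2.0
- 2.0
- 2.0
- 2.0
- 2.0
- 2.0
- 2.0
- 2.0
- 2.0
- 2.0
- 2.0
- 2.0
quadrat_area_m2: 1.0
bed_abundance_mult:
- 1.0
- 1.0
- 1.0
- 5.0
- 5.0
- 1.5
- 1.5
- 1.5
- 1.5
- 0.7
- 1.0
- 1.0
- 1.0
n_offquadrat_per_bed:
- 30.0
- 30.0
- 30.0
- 30.0
- 30.0
- 30.0
- 30.0
- 30.0
- 30.0
- 30.0
- 0.0
- 0.0
- 5.0
fragment_fraction: 0.45
indet_fraction: 0.3
boundary_pair:
- B4
- B5
model_window:
- B1
- B2
- B3
- B4
- B5
- B6
- B7
- B8
- B9
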