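# Example crsoil assessment configuration. Every field is optional; omitted
# fields take the package defaults (see ?default_config).
screening_value: 2500        # mg/kg, total Cr in industrial land
toxic_response_coefficient: 2   # Hakanson Tn for Cr

background:
  national_default: 61       # mg/kg national soil Cr background
  per_province:              # provincial overrides (examples, user-supplied)
    Zhejiang: 52.9

# area_map: {}               # province -> hotspot area; empty = shipped map

receptors:                   # exposure parameters, overridable per group
  child:
    IngR: 200                # soil ingestion, mg/day
    InhR: 7.6                # inhalation, m3/day
    SA: 2800                 # exposed skin, cm2
    AF: 0.2                  # adherence, mg/(cm2 day)
    ABS: 0.001               # dermal absorption fraction
    EF: 350                  # days/year
    ED: 6                    # years
    BW: 15                   # kg
    AT: 2190                 # days
    PEF: 1.36e+9             # m3/kg
  adult_male:
    {IngR: 100, InhR: 19, SA: 5700, AF: 0.07, ABS: 0.001,
     EF: 350, ED: 24, BW: 70, AT: 8760}
  adult_female:
    {IngR: 100, InhR: 14.5, SA: 5700, AF: 0.07, ABS: 0.001,
     EF: 350, ED: 24, BW: 57, AT: 8760}

toxicity:
  rfd_ing: 3.0e-3            # mg/(kg day)
  rfd_derm: 7.5e-5
  rfd_inh: 2.86e-5

pathways: [ing, derm, inh]

mc:
  n_iter: 10000
  seed: 1
  params:                    # stochastic inputs; everything else stays fixed
    cn: {kind: lognormal, meanlog: 5.0, sdlog: 1.4}
    BW: {kind: normal, mean: 15, sd: 2, truncation: [5, 40]}

trend:
  degree: 2                  # 2 (quadratic) or 3 (cubic)
  log_base: log10            # log10 or ln
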