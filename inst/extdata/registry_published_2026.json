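{
  "name": "published-2026",
  "version": "1.0",
  "provenance": "Published parameter estimates for natural Larix gmelinii secondary forests in northeast China; climate exponents stored by role (sci_exp on SCI, mai_exp on 1/MAI) as selected by consistency with the published age-80 simulation table; stage dummy coding likewise defaults to the table-consistent non-cumulative scheme.",
  "sci": {
    "a0": 22.1148,
    "a1": 0.0046,
    "a2": 0.4059,
    "reference_age": 80
  },
  "self_thinning": {
    "b0": 10.7253,
    "b1": -1.2338,
    "d0_cm": 20
  },
  "sdi_dynamics": {
    "b2": 77.7472,
    "b3": 37.3025,
    "b4": 0.0834
  },
  "bas_base": {
    "c": 14.7891,
    "k": 0.035
  },
  "bas_stand": {
    "c0": 6.0329,
    "c1": 0.5166,
    "k0": 0.0317,
    "k1": 1.9227
  },
  "bas_climate": {
    "c0": 22.8911,
    "sci_exp": 0.4972,
    "mai_exp": 0.3015,
    "k0": 0.0276,
    "k1": 1.8271
  },
  "bas_stage": {
    "c0": 12.5211,
    "c01": 2.2253,
    "c02": 3.9381,
    "sci_exp": 0.5966,
    "mai_exp": 0.2476,
    "k0": 0.0362,
    "k01": -0.0109,
    "k02": -0.0207,
    "k1": 1.6959,
    "coding": "non_cumulative"
  },
  "volume": {
    "d0": 2.9095,
    "d1": 1.0096,
    "d2": 0.3066
  },
  "biomass": {
    "root":   { "e0": -1.1579, "e1": 1.0676, "e2": 0.545 },
    "stem":   { "e0": 0.0928,  "e1": 1.0536, "e2": 0.4248 },
    "branch": { "e0": -2.004,  "e1": 1.0918, "e2": 0.3687 },
    "leaf":   { "e0": -1.869,  "e1": 1.0085, "e2": -0.0696 }
  },
  "carbon_fractions": {
    "root": 0.52,
    "stem": 0.47,
    "branch": 0.51,
    "leaf": 0.52
  },
  "wood_density": {
    "commercial": 0.6,
    "fuel": 0.6,
    "bark": 0.3
  },
  "q_policy": {
    "mode": "stage_linear",
    "fixed_q": 1.45,
    "stage_q": [1.7, 1.45, 1.2],
    "range": [1.2, 1.7]
  },
  "diameter_grid": {
    "min_midpoint_cm": 6,
    "max_midpoint_cm": 40,
    "width_cm": 2,
    "min_share": 1e-04
  }
}
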