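parameters:
  geometry:
    length_cm: 20.0
    area_csf_cm2: 0.35
    area_tissue_cm2: 0.3
    n_elements: 100
  transport:
    dispersion_cm2_min: 0.1
    clearance_per_min:
      k1: 0.001
      k2: 0.0002
      k3: 0.001
      k4: 0.0002
      k5: 0.02
      k6: 0.001
  exchange:
    U:
      1_2: 0.05
      1_5: 0.02
      1_3: 0.05
      2_5: 0.005
      3_4: 0.02
      4_5: 0.01
      5_6: 0.05
    beta:
      1_2: 0.1
      1_5: 0.0
      2_5: 0.1
      3_4: 0.1
      4_5: 0.2
      5_6: 0.5
  volumes:
    c3: 4.0
    c4: 70.0
    c5: 160.0
    c6: 2000.0
  partition:
    regions:
      pons:
        volume_ml: 1.8
        phi: 0.06
      hippocampus:
        volume_ml: 1.2
        phi: 0.04
      cerebellum:
        volume_ml: 5.8
        phi: 0.15
      cortex:
        volume_ml: 61.2
        phi: 0.75
  landmarks:
    lumbar: 0.15
    thoracic: 0.5
    cervical: 0.9
schedule:
  horizon_min: 10080.0
  events:
  - start_min: 0.0
    volume_ml: 1.0
    dose_ug: 12000.0
    site_cm: 3.0
    duration_min: 1.0
    spread_cm: 2.0
  - start_min: 1.0
    volume_ml: 0.25
    dose_ug: 0.0
    site_cm: 3.0
    duration_min: 1.0
    spread_cm: 2.0
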