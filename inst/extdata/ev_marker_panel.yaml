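units:
  concentration: pmol/ml
  time: minutes
  collision_energy: eV
analytes:
- analyte_id: ALB
  protein_name: Serum albumin
  misev_category: 3
  marker_polarity: contaminant
  peptide_sequence: LVNEVTEFAK
  sil_spike_conc: 10.0
- analyte_id: CD81
  protein_name: CD81 antigen
  misev_category: 1
  marker_polarity: positive_ev
  peptide_sequence: QFYDQALQQAVVDDDANNAK
  sil_spike_conc: 0.4
- analyte_id: CD9
  protein_name: CD9 antigen
  misev_category: 1
  marker_polarity: positive_ev
  peptide_sequence: DVLETFTVK
  sil_spike_conc: 0.1
- analyte_id: CANX
  protein_name: Calnexin
  misev_category: 4
  marker_polarity: contaminant
  peptide_sequence: IVDDWANDGWGLK
  sil_spike_conc: 0.2
- analyte_id: TSG101
  protein_name: Tumor susceptibility gene 101 protein
  misev_category: 2
  marker_polarity: positive_ev
  peptide_sequence: GVIDLDVFLK
  sil_spike_conc: 0.2
transitions:
- analyte_id: ALB
  form: SIL
  precursor_mz: 579.3
  product_mz: 603.3
  product_label: y5+
  role: qualifier
  collision_energy: 18.8
  expected_rt: 20.7
- analyte_id: ALB
  form: SIL
  precursor_mz: 579.3
  product_mz: 702.4
  product_label: y6+
  role: qualifier
  collision_energy: 18.8
  expected_rt: 20.7
- analyte_id: ALB
  form: SIL
  precursor_mz: 579.3
  product_mz: 945.5
  product_label: y8+
  role: quantifier
  collision_energy: 18.8
  expected_rt: 20.7
- analyte_id: ALB
  form: light
  precursor_mz: 575.3
  product_mz: 595.3
  product_label: y5+
  role: qualifier
  collision_energy: 18.8
  expected_rt: 20.7
- analyte_id: ALB
  form: light
  precursor_mz: 575.3
  product_mz: 694.4
  product_label: y6+
  role: qualifier
  collision_energy: 18.8
  expected_rt: 20.7
- analyte_id: ALB
  form: light
  precursor_mz: 575.3
  product_mz: 937.5
  product_label: y8+
  role: quantifier
  collision_energy: 18.8
  expected_rt: 20.7
- analyte_id: CD81
  form: SIL
  precursor_mz: 754.4
  product_mz: 870.4
  product_label: y8+
  role: qualifier
  collision_energy: 17.3
  expected_rt: 23.9
- analyte_id: CD81
  form: SIL
  precursor_mz: 754.4
  product_mz: 969.4
  product_label: y9+
  role: quantifier
  collision_energy: 17.3
  expected_rt: 23.9
- analyte_id: CD81
  form: SIL
  precursor_mz: 754.4
  product_mz: 1068.5
  product_label: y10+
  role: qualifier
  collision_energy: 17.3
  expected_rt: 23.9
- analyte_id: CD81
  form: light
  precursor_mz: 751.7
  product_mz: 862.4
  product_label: y8+
  role: qualifier
  collision_energy: 17.3
  expected_rt: 23.9
- analyte_id: CD81
  form: light
  precursor_mz: 751.7
  product_mz: 961.4
  product_label: y9+
  role: quantifier
  collision_energy: 17.3
  expected_rt: 23.9
- analyte_id: CD81
  form: light
  precursor_mz: 751.7
  product_mz: 1060.5
  product_label: y10+
  role: qualifier
  collision_energy: 17.3
  expected_rt: 23.9
- analyte_id: CD9
  form: SIL
  precursor_mz: 530.3
  product_mz: 603.4
  product_label: y5+
  role: qualifier
  collision_energy: 22.3
  expected_rt: 24.3
- analyte_id: CD9
  form: SIL
  precursor_mz: 530.3
  product_mz: 732.4
  product_label: y6+
  role: qualifier
  collision_energy: 22.3
  expected_rt: 24.3
- analyte_id: CD9
  form: SIL
  precursor_mz: 530.3
  product_mz: 846.5
  product_label: y7+
  role: quantifier
  collision_energy: 22.3
  expected_rt: 24.3
- analyte_id: CD9
  form: light
  precursor_mz: 526.3
  product_mz: 595.4
  product_label: y5+
  role: qualifier
  collision_energy: 22.3
  expected_rt: 24.3
- analyte_id: CD9
  form: light
  precursor_mz: 526.3
  product_mz: 724.4
  product_label: y6+
  role: qualifier
  collision_energy: 22.3
  expected_rt: 24.3
- analyte_id: CD9
  form: light
  precursor_mz: 526.3
  product_mz: 837.5
  product_label: y7+
  role: quantifier
  collision_energy: 22.3
  expected_rt: 24.3
- analyte_id: CANX
  form: SIL
  precursor_mz: 748.9
  product_mz: 797.4
  product_label: y7+
  role: qualifier
  collision_energy: 24.1
  expected_rt: 27.2
- analyte_id: CANX
  form: SIL
  precursor_mz: 748.9
  product_mz: 868.4
  product_label: y8+
  role: quantifier
  collision_energy: 24.1
  expected_rt: 27.2
- analyte_id: CANX
  form: SIL
  precursor_mz: 748.9
  product_mz: 1054.5
  product_label: y9+
  role: qualifier
  collision_energy: 24.1
  expected_rt: 27.2
- analyte_id: CANX
  form: light
  precursor_mz: 744.9
  product_mz: 789.4
  product_label: y7+
  role: qualifier
  collision_energy: 24.1
  expected_rt: 27.2
- analyte_id: CANX
  form: light
  precursor_mz: 744.9
  product_mz: 860.4
  product_label: y8+
  role: quantifier
  collision_energy: 24.1
  expected_rt: 27.2
- analyte_id: CANX
  form: light
  precursor_mz: 744.9
  product_mz: 1046.5
  product_label: y9+
  role: qualifier
  collision_energy: 24.1
  expected_rt: 27.2
- analyte_id: TSG101
  form: SIL
  precursor_mz: 563.8
  product_mz: 742.5
  product_label: y6+
  role: qualifier
  collision_energy: 18.4
  expected_rt: 32.5
- analyte_id: TSG101
  form: SIL
  precursor_mz: 563.8
  product_mz: 857.5
  product_label: y7+
  role: quantifier
  collision_energy: 18.4
  expected_rt: 32.5
- analyte_id: TSG101
  form: SIL
  precursor_mz: 563.8
  product_mz: 970.6
  product_label: y8+
  role: qualifier
  collision_energy: 18.4
  expected_rt: 32.5
- analyte_id: TSG101
  form: light
  precursor_mz: 559.8
  product_mz: 734.4
  product_label: y6+
  role: qualifier
  collision_energy: 18.4
  expected_rt: 32.5
- analyte_id: TSG101
  form: light
  precursor_mz: 559.8
  product_mz: 849.5
  product_label: y7+
  role: quantifier
  collision_energy: 18.4
  expected_rt: 32.5
- analyte_id: TSG101
  form: light
  precursor_mz: 559.8
  product_mz: 962.6
  product_label: y8+
  role: qualifier
  collision_energy: 18.4
  expected_rt: 32.5
calibration_ranges:
- analyte_id: ALB
  low: 2.0
  high: 80.0
- analyte_id: CD81
  low: 0.2
  high: 8.0
- analyte_id: CD9
  low: 0.02
  high: 0.8
- analyte_id: CANX
  low: 0.04
  high: 1.6
- analyte_id: TSG101
  low: 0.04
  high: 1.6
instrument_settings:
  time_segments_min:
  - 0-22
  - 22-26
  - 26-30
  - 30-48
  delta_emv_v:
  - 300.0
  - 300.0
  - 300.0
  - 300.0
  capillary_voltage_v:
  - 3000.0
  - 2500.0
  - 3000.0
  - 3000.0
  nebulizer_pressure_psi:
  - 30.0
  - 25.0
  - 30.0
  - 30.0
  nozzle_voltage_v:
  - 1000.0
  - 500.0
  - 500.0
  - 500.0
  cell_accelerator_voltage_v:
  - 5.0
  - 3.0
  - 5.0
  - 4.0
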