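fields_per_well: 10
pixel_size_um: 0.6
wells:
- well: B02
  condition: basal
  role: negative_control
- well: B03
  condition: oxLDL
  role: positive_control
- well: B04
  condition: vehicle
  role: vehicle_control
- well: B05
  condition: drug_1nM
  role: treatment
  dose_nM: 1.0
- well: B06
  condition: drug_10nM
  role: treatment
  dose_nM: 10.0
- well: B07
  condition: drug_100nM
  role: treatment
  dose_nM: 100.0
- well: B08
  condition: drug_1uM
  role: treatment
  dose_nM: 1000.0
- well: C02
  condition: basal
  role: negative_control
- well: C03
  condition: oxLDL
  role: positive_control
- well: C04
  condition: vehicle
  role: vehicle_control
- well: C05
  condition: drug_1nM
  role: treatment
  dose_nM: 1.0
- well: C06
  condition: drug_10nM
  role: treatment
  dose_nM: 10.0
- well: C07
  condition: drug_100nM
  role: treatment
  dose_nM: 100.0
- well: C08
  condition: drug_1uM
  role: treatment
  dose_nM: 1000.0
- well: D02
  condition: background
  role: background_well
- well: D03
  condition: background
  role: background_well
- well: E01
  condition: unused
  role: empty
- well: E02
  condition: unused
  role: empty
- well: E03
  condition: unused
  role: empty
- well: E04
  condition: unused
  role: empty
- well: E05
  condition: unused
  role: empty
- well: E06
  condition: unused
  role: empty
- well: E07
  condition: unused
  role: empty
- well: E08
  condition: unused
  role: empty
- well: E09
  condition: unused
  role: empty
- well: E10
  condition: unused
  role: empty
- well: E11
  condition: unused
  role: empty
- well: E12
  condition: unused
  role: empty
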