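arms:
- name: control
  counts: control_counts.csv
  cost: 3978.18
  cost_sd: 1763.79
  n_patients: 30
- name: anthracycline_trastuzumab
  counts: anthracycline_trastuzumab_counts.csv
  cost: 41308.19
  cost_sd: 5588.75
  n_patients: 38
- name: no_anthracycline_trastuzumab
  counts: no_anthracycline_trastuzumab_counts.csv
  cost: 43664.83
  cost_sd: 6672.79
  n_patients: 14
- name: anthracycline_taxane_trastuzumab
  counts: anthracycline_taxane_trastuzumab_counts.csv
  cost: 47304.25
  cost_sd: 7125.32
  n_patients: 96
utilities:
  stable: 0.62
  recurrence: 0.767
  metastasis: 0.692
discount:
  cost: 0.03
  qaly: 0.03
horizon:
  mode: fixed
  n_cycles: 20.0
thresholds:
- 20000.0
- 40000.0
- 60000.0
psa:
  'n': 1000.0
dsa:
  delta: 0.1
horizons:
- 5.0
- 10.0
- 15.0
- 20.0
seed: 1.0
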