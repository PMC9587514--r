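description: Seven-step ICG/Intralipid dilution-series presets; feed icg_um and intralipid_pct
  to phantom_scene().
presets:
- name: icg_1_4_0
  icg_um: 1290.4
  intralipid_pct: 16.0
- name: icg_1_4_1
  icg_um: 1075.3
  intralipid_pct: 13.33
- name: icg_1_4_2
  icg_um: 921.7
  intralipid_pct: 11.43
- name: icg_1_4_3
  icg_um: 806.5
  intralipid_pct: 10.0
- name: icg_1_4_4
  icg_um: 716.9
  intralipid_pct: 8.89
- name: icg_1_4_5
  icg_um: 645.2
  intralipid_pct: 8.0
- name: icg_1_4_95
  icg_um: 64.5
  intralipid_pct: 0.8
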