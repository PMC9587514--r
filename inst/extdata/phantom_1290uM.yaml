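layers:
- name: interface
  top_um: 50.0
  thickness_um: 4.0
  reflectivity: 4.0
  depolarization: 0.0
  absorption_scale: 1.0
- name: medium
  top_um: 54.0
  thickness_um: 200.0
  reflectivity: 1.0
  depolarization: 0.8
  absorption_scale: 1.0
  absorption:
    wavelength_nm:
    - 803.0
    - 807.473684210526
    - 811.947368421053
    - 816.421052631579
    - 820.894736842105
    - 825.368421052632
    - 829.842105263158
    - 834.315789473684
    - 838.789473684211
    - 843.263157894737
    - 847.736842105263
    - 852.210526315789
    - 856.684210526316
    - 861.157894736842
    - 865.631578947368
    - 870.105263157895
    - 874.578947368421
    - 879.052631578947
    - 883.526315789474
    - 888.0
    mu_a:
    - 0.00998368679
    - 0.00997505519
    - 0.009804924056
    - 0.009481514831
    - 0.009020192184
    - 0.00844225411
    - 0.007773303368
    - 0.007041373504
    - 0.006274999764
    - 0.005501417611
    - 0.004745042214
    - 0.004026336935
    - 0.00336112541
    - 0.002760348313
    - 0.002230219577
    - 0.001772702791
    - 0.001386209276
    - 0.001066414988
    - 0.000807101673
    - 0.000600945133
noise_floor: 0.05
scatterer_density: 0.3
refractive_index: 1.38
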