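eps: 0.478618615127
male:
  f_active:
    PCT: 0.30302561
    PST: 0.14927069
    ThinLimbs: 0.0
    mTAL: 0.48494906
    cTAL: 0.44277765
    DCT: 0.30248797
    CNT: 0.57944309
    CCD: 0.57944309
    OMCD: 0.09762633
    IMCD: 0.09762636
  f_passive:
    PCT: 0.24
    PST: 0.08899012
  beta:
    PT: 0.08708668
    TAL: 0.40601404
    DCT: 0.0378346
    ENaC: 0.78602661
  water_frac_distal: 0.55
female:
  f_active:
    PCT: 0.33469266
    PST: 0.01
    ThinLimbs: 0.0
    mTAL: 0.54663994
    cTAL: 0.32113465
    DCT: 0.65462646
    CNT: 0.53893065
    CCD: 0.37985424
    OMCD: 0.10998003
    IMCD: 0.04767178
  f_passive:
    PCT: 0.04599389
    PST: 0.24
  beta:
    PT: 0.01
    TAL: 0.27734947
    DCT: 0.01
    ENaC: 0.95817076
  water_frac_distal: 0.55
fit:
  report:
    id:
    - tna_pt_swing_male
    - tna_tal_swing_male
    - tna_dt_swing_male
    - tna_pt_swing_female
    - tna_tal_swing_female
    - tna_dt_swing_female
    - cortex_mf_zt2
    - cortex_mf_zt14
    - medulla_fm_zt2
    - medulla_fm_zt14
    - qo2_whole_mf
    - qo2_swing_whole_male
    - qo2_swing_cortex_male
    - qo2_swing_medulla_male
    - qo2_swing_whole_female
    - qo2_swing_cortex_female
    - qo2_swing_medulla_female
    - urine_frac_male
    - urine_na_fm
    - urine_v_fm
    - cnt_delivery_swing_male
    - cnt_delivery_swing_female
    - diuretic_qo2_zt2_male
    - diuretic_qo2_zt2_female
    - diuretic_qo2_zt14_male
    - diuretic_qo2_zt14_female
    - cnt_delivery_mf_zt0
    - cnt_delivery_mf_zt12
    - mtal_tna_fm
    - share_pt_male
    - share_tal_male
    - share_dt_male
    - share_pt_female
    - share_tal_female
    - share_dt_female
    - urine_v_male
    - po2_gain_fm_zt2
    - po2_gain_fm_zt14
    - enac_fc_mf_zt0
    - enac_fc_mf_zt12
    target:
    - 1.47
    - 1.34
    - 1.16
    - 1.38
    - 1.49
    - 1.26
    - 1.51
    - 1.51
    - 1.16
    - 1.16
    - 1.12
    - 1.43
    - 1.39
    - 1.48
    - 1.43
    - 1.39
    - 1.48
    - 0.01
    - 0.95
    - 0.95
    - 1.35
    - 1.09
    - 0.908
    - 0.908
    - 0.916
    - 0.916
    - 1.98
    - 1.61
    - 1.2
    - 0.65
    - 0.25
    - 0.09
    - 0.53
    - 0.33
    - 0.13
    - 10.0
    - 1.15
    - 1.15
    - 1.2
    - 1.2
    model:
    - 1.187841233933
    - 1.217038628524
    - 1.156900530815
    - 1.154966000423
    - 1.245970551737
    - 1.16591907204
    - 1.511618532272
    - 1.546466698402
    - 1.164682082203
    - 1.177883883446
    - 1.115190420686
    - 1.155110223096
    - 1.148945307878
    - 1.167168003826
    - 1.142592517018
    - 1.11732383037
    - 1.195486555533
    - 0.010035775535
    - 0.95383493758
    - 0.95383493758
    - 1.351751888733
    - 1.188119809541
    - 0.926077205599
    - 0.926276074979
    - 0.902315754705
    - 0.906481455377
    - 1.886950001541
    - 1.658531195799
    - 1.199333096914
    - 0.651904698408
    - 0.248192682598
    - 0.089866843459
    - 0.535514910702
    - 0.321530310195
    - 0.130989187438
    - 10.116061739545
    - 1.149551534454
    - 1.136320625981
    - 1.78173337765
    - 2.34670272279
    weight:
    - 0.3
    - 0.3
    - 0.3
    - 0.3
    - 0.3
    - 0.3
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    - 0.3
    - 0.3
    - 0.3
    - 0.3
    - 0.3
    - 0.3
    - 1.0
    - 1.0
    - 1.0
    - 3.0
    - 3.0
    - 3.0
    - 3.0
    - 3.0
    - 3.0
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    - 0.3
    - 2.0
    - 2.0
    - 2.0
    - 2.0
    tol:
    - 0.03
    - 0.03
    - 0.03
    - 0.03
    - 0.03
    - 0.03
    - 0.03
    - 0.03
    - 0.03
    - 0.03
    - 0.04
    - 0.03
    - 0.03
    - 0.03
    - 0.03
    - 0.03
    - 0.03
    - 0.005
    - .na.real
    - .na.real
    - 0.05
    - 0.05
    - 0.02
    - 0.02
    - 0.02
    - 0.02
    - .na.real
    - .na.real
    - .na.real
    - .na.real
    - .na.real
    - .na.real
    - .na.real
    - .na.real
    - .na.real
    - .na.real
    - .na.real
    - .na.real
    - .na.real
    - .na.real
    residual:
    - -0.282158766067
    - -0.122961371476
    - -0.003099469185
    - -0.225033999577
    - -0.244029448263
    - -0.09408092796
    - 0.001618532272
    - 0.036466698402
    - 0.004682082203
    - 0.017883883446
    - -0.004809579314
    - -0.274889776904
    - -0.241054692122
    - -0.312831996174
    - -0.287407482982
    - -0.27267616963
    - -0.284513444467
    - 3.577553526281e-05
    - 3.834937579576e-03
    - 3.834937579576e-03
    - 1.75188873279e-03
    - 9.811980954105e-02
    - 1.807720559946e-02
    - 1.82760749786e-02
    - -1.368424529453e-02
    - -9.518544622826e-03
    - -9.304999845935e-02
    - 4.85311957993e-02
    - -6.669030863282e-04
    - 1.90469840822e-03
    - -1.807317402308e-03
    - -1.331565411744e-04
    - 5.514910702158e-03
    - -8.469689804645e-03
    - 9.891874384368e-04
    - 1.160617395449e-01
    - -4.484655461672e-04
    - -1.36793740194e-02
    - 5.817333776498e-01
    - 1.14670272279e+00
    within_tol:
    - no
    - no
    - yes
    - no
    - no
    - no
    - yes
    - no
    - yes
    - yes
    - yes
    - no
    - no
    - no
    - no
    - no
    - no
    - yes
    - .na
    - .na
    - yes
    - no
    - yes
    - yes
    - yes
    - yes
    - .na
    - .na
    - .na
    - .na
    - .na
    - .na
    - .na
    - .na
    - .na
    - .na
    - .na
    - .na
    - .na
    - .na
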