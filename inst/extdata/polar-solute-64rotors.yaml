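kind: dipole_bath
thermo:
  temperature: 300.0
solute:
  coordinates:
  - - 1.19999999999999996
    - 0.0
    - 0.0
  - - -1.19999999999999996
    - 0.0
    - 0.0
  - - 0.0
    - 1.0
    - 0.59999999999999998
  - - 0.0
    - -1.0
    - 0.59999999999999998
  base_charges:
  - 0.34999999999999998
  - -0.34999999999999998
  - 0.20000000000000001
  - -0.20000000000000001
  net_charge: 0.0
  atom_labels:
  - A1
  - A2
  - A3
  - A4
  heavy:
  - yes
  - yes
  - yes
  - yes
solvent:
  site_positions:
  - - 0.35953269019774364
    - -0.92472225272195829
    - 3.875
  - - -1.5164316450324149
    - 0.74820456156340298
    - 3.625
  - - 2.06137812664560727
    - 0.60007934390965811
    - 3.375
  - - -1.29632321737339251
    - -2.13399182662415443
    - 3.125
  - - -0.54089732817172997
    - 2.72796720661680325
    - 2.875
  - - 2.43265944520368249
    - -1.78648902142199373
    - 2.625
  - - -3.19977542902853074
    - -0.34758049971953814
    - 2.375
  - - 2.23701922732461211
    - 2.54560797778840886
    - 2.125
  - - 0.07301021162423743
    - -3.5325691088779263
    - 1.875
  - - -2.52411233425637516
    - 2.64352641826308066
    - 1.625
  - - 3.74784904947370601
    - -0.25100299272924986
    - 1.375
  - - -2.99735681893146699
    - -2.39796311481328628
    - 1.125
  - - 0.60028991845369517
    - 3.8566860144174111
    - 0.875
  - - 2.18897268084420116
    - -3.28903840088828225
    - 0.625
  - - -3.86638889881867387
    - 0.95415506239380321
    - 0.375
  - - 3.50922557155183856
    - 1.91564894695418375
    - 0.125
  - - -1.29359145173902612
    - -3.78298772876515166
    - -0.125
  - - -1.59524308333397236
    - 3.6489141542485104
    - -0.375
  - - 3.61227646558394699
    - -1.60026052134905505
    - -0.625
  - - -3.69928778586681872
    - -1.24484733093523214
    - -0.875
  - - 1.85563526199515794
    - 3.36020725170935908
    - -1.125
  - - 0.88217269713037361
    - -3.65118423698910632
    - -1.375
  - - -3.03285584996915469
    - 2.03989225041615274
    - -1.625
  - - 3.49389489013847587
    - 0.52637771292508817
    - -1.875
  - - -2.12992994572693384
    - -2.63586293769149904
    - -2.125
  - - -0.19940724045294644
    - 3.2124152521825291
    - -2.375
  - - 2.17271143806431377
    - -2.09492243457950078
    - -2.625
  - - -2.78016722659762427
    - 0.07102951606532751
    - -2.875
  - - 1.88359252998526983
    - 1.63904062822850416
    - -3.125
  - - -0.24226074603707878
    - -2.1332333981375684
    - -3.375
  - - -0.99424149802793804
    - 1.36779342139051163
    - -3.625
  - - 0.97225765217640447
    - -0.19771205776185174
    - -3.875
  - - 0.58424062157133339
    - -1.50267366067318231
    - 6.296875
  - - -2.46420142317767432
    - 1.21583241254052976
    - 5.890625
  - - 3.34973945579911181
    - 0.97512893385319444
    - 5.484375
  - - -2.1065252282317628
    - -3.46773671826425112
    - 5.078125
  - - -0.87895815827906121
    - 4.43294671075230529
    - 4.671875
  - - 3.95307159845598388
    - -2.90304465981073978
    - 4.265625
  - - -5.19963507217136289
    - -0.56481831204424948
    - 3.859375
  - - 3.63515624440249452
    - 4.13661296390616418
    - 3.453125
  - - 0.11864159388938583
    - -5.74042480192662996
    - 3.046875
  - - -4.10168254316660974
    - 4.29573042967750585
    - 2.640625
  - - 6.09025470539477265
    - -0.407879863185031
    - 2.234375
  - - -4.87070483076363381
    - -3.89669006157159004
    - 1.828125
  - - 0.97547111748725468
    - 6.26711477342829326
    - 1.421875
  - - 3.55708060637182699
    - -5.34468740144345844
    - 1.015625
  - - -6.28288196058034476
    - 1.55050197638993015
    - 0.609375
  - - 5.702491553771738
    - 3.11292953880054846
    - 0.203125
  - - -2.10208610907591753
    - -6.14735505924337122
    - -0.203125
  - - -2.592270010417705
    - 5.92948550065382918
    - -0.609375
  - - 5.8699492565739142
    - -2.60042334719221468
    - -1.015625
  - - -6.01134265203357998
    - -2.02287691276975234
    - -1.421875
  - - 3.01540730074213181
    - 5.46033678402770839
    - -1.828125
  - - 1.43353063283685711
    - -5.93317438510729822
    - -2.234375
  - - -4.92839075619987632
    - 3.31482490692624809
    - -2.640625
  - - 5.67757919647502352
    - 0.85536378350326825
    - -3.046875
  - - -3.46113616180626771
    - -4.28327727374868594
    - -3.453125
  - - -0.32403676573603796
    - 5.22017478479661001
    - -3.859375
  - - 3.53065608685450982
    - -3.40424895619168888
    - -4.265625
  - - -4.5177717432211395
    - 0.1154229636061572
    - -4.671875
  - - 3.06083786122606361
    - 2.66344102087131906
    - -5.078125
  - - -0.393673712310253
    - -3.4665042719735486
    - -5.484375
  - - -1.61564243429539922
    - 2.22266430975958151
    - -5.890625
  - - 1.57991868478665731
    - -0.3212820938630091
    - -6.296875
  dipole_magnitude: 0.48999999999999999
  rotational_friction: 2000.0
  inertia: 600.0
high_level:
  response_coefficients:
  - -0.0015
  - -0.0015
  - -0.0015
  - -0.0015
  level_offset: 0.0
labels:
  low: MM
  high: SQM-like
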