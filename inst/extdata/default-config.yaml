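schema:
  contrast: gender
  contrast_levels:
  - male
  - female
  covariates:
  - name: grade
    kind: ordinal
    levels:
    - 5 and 6
    - '7'
    - '8'
    - '9'
    - 10 and 11
  - name: urban_rural
    kind: ordinal
    levels:
    - Rural
    - Small
    - Medium
    - Large
  - name: ses_quintile
    kind: ordinal
    levels:
    - Q1
    - Q2
    - Q3
    - Q4
    - Q5
  - name: family_structure
    kind: nominal
    levels:
    - Mother and father
    - Mother and partner
    - Mother only
    - Father and partner
    - Father only
    - Other
  - name: immigration
    kind: ordinal
    levels:
    - Immigrated <5 years ago
    - Immigrated 5+ years ago
    - Born in Canada
  - name: affluence
    kind: ordinal
    levels:
    - High
    - Average
    - Low
  - name: religious
    kind: nominal
    levels:
    - 'Yes'
    - 'No'
  - name: ethnicity
    kind: nominal
    levels:
    - White
    - Black
    - Indigenous
    - East Asian
    - West Asian and Arab
    - Other
  outcomes:
  - name: psychosomatic
    measure: continuous
    range:
    - 0.0
    - 40.0
    disadvantage_sign: -1.0
  - name: depression
    measure: binary
    range:
    - 0.0
    - 1.0
    disadvantage_sign: 1.0
  - name: diagnosis
    measure: binary
    range:
    - 0.0
    - 1.0
    disadvantage_sign: 1.0
n_per_group:
- 10349
- 10872
marginals:
  grade:
  - - 0.197
    - 0.207
    - 0.204
    - 0.222
    - 0.17
  - - 0.179179179179
    - 0.213213213213
    - 0.208208208208
    - 0.222222222222
    - 0.177177177177
  urban_rural:
  - - 0.042957042957
    - 0.525474525475
    - 0.174825174825
    - 0.256743256743
  - - 0.04
    - 0.512
    - 0.174
    - 0.274
  ses_quintile:
  - - 0.175
    - 0.207
    - 0.2
    - 0.2
    - 0.218
  - - 0.19
    - 0.206
    - 0.194
    - 0.197
    - 0.213
  family_structure:
  - - 0.723
    - 0.048
    - 0.153
    - 0.01
    - 0.032
    - 0.034
  - - 0.705294705295
    - 0.061938061938
    - 0.15984015984
    - 0.012987012987
    - 0.027972027972
    - 0.031968031968
  immigration:
  - - 0.072
    - 0.184
    - 0.744
  - - 0.067
    - 0.149
    - 0.784
  affluence:
  - - 0.557
    - 0.358
    - 0.085
  - - 0.512
    - 0.396
    - 0.092
  religious:
  - - 0.241
    - 0.759
  - - 0.257
    - 0.743
  ethnicity:
  - - 0.666
    - 0.036
    - 0.078
    - 0.06
    - 0.014
    - 0.146
  - - 0.66033966034
    - 0.033966033966
    - 0.076923076923
    - 0.058941058941
    - 0.013986013986
    - 0.155844155844
models:
- outcome: psychosomatic
  overall:
  - 32.9
  - 29.2
  subgroup:
  - 31.6
  - 26.6
  rule:
  - covariate: grade
    op: ge
    value: '9'
  - covariate: affluence
    op: ge
    value: Low
  sd: 6.5
- outcome: depression
  overall:
  - 0.225
  - 0.401
  subgroup:
  - 0.294
  - 0.537
  rule:
  - covariate: grade
    op: ge
    value: '9'
  - covariate: affluence
    op: ge
    value: Low
- outcome: diagnosis
  overall:
  - 0.028
  - 0.093
  subgroup:
  - 0.04
  - 0.165
  rule:
  - covariate: grade
    op: ge
    value: '9'
  - covariate: affluence
    op: ge
    value: Low
missing_rates:
  grade:
  - 9.662769349696e-05
  - 0.0e+00
  ses_quintile:
  - 0.206590008696
  - 0.16087196468
  family_structure:
  - 0.026765871099
  - 0.019131714496
  immigration:
  - 0.06271137308
  - 0.066961000736
  affluence:
  - 0.144361774084
  - 0.117273730684
  religious:
  - 0.053918252971
  - 0.037987490802
  ethnicity:
  - 0.017586240216
  - 0.016188373804
seed: 1
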