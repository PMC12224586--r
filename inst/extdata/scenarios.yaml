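# The ten default sodium-reduction counterfactual scenarios.
# kind: target_level (mg/day ceiling) | absolute_delta (mg/day reduction)
#       | proportional (fraction of intake removed)
# param: scalar applied to every DRI age/sex group, or a mapping keyed by
#        "<sex>.<group>" (e.g. "male.19-30") for group-specific effects.
scenarios:
  - id: S1
    kind: target_level
    param: 1500
    label: "Meeting AI sodium intake recommendations (1,500 mg/day)"
  - id: S2
    kind: target_level
    param: 2000
    label: "Meeting WHO sodium intake recommendations (2,000 mg/day)"
  - id: S3
    kind: absolute_delta
    param: 459
    label: "Sodium reduction targets for packaged foods (2,300 mg/day)"
  - id: S4
    kind: proportional
    param: 0.047
    label: "FOPL: changes in food & beverage purchases (Chilean experience)"
  - id: S5
    kind: proportional
    param: 0.064
    label: "FOPL: WHO cost-effectiveness criteria"
  - id: S6
    kind: proportional
    param: 0.078
    label: "FOPL: systematic review and network meta-analysis"
  - id: S7
    kind: absolute_delta
    param: 73
    label: "FOPL: food substitution, 30% of adult consumers"
  - id: S8
    kind: absolute_delta
    param: 131
    label: "FOPL: food substitution, 50% of adult consumers"
  - id: S9
    kind: absolute_delta
    param: 182
    label: "FOPL: food substitution, 70% of adult consumers"
  - id: S10
    kind: absolute_delta
    param: 259
    label: "FOPL: food substitution, all adult consumers"
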