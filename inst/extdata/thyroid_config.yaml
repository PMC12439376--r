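# Synthetic template configuration: feature order and types follow the
# published case-study schema; fuzzy knots are illustrative placeholders
# consistent with the worked example (age ramp 40-50 y, nodule ramp 10-20 mm).
feature_order:
- class
- gender
- age
- thyroiditis
- struma
- nodule_mm
target: target
positive_class: '1'
negative_class: '0'
threshold: 0.5
variables:
  class:
    type: categorical
    values:
    - TIR2
    - TIR3A
    - TIR3B
    - TIR4
    - TIR5
  gender:
    type: binary
    values:
    - Female
    - Male
  age:
    type: fuzzy
    universe:
    - 18.0
    - 95.0
    crisp_threshold: 50.0
    sets:
    - name: Under50
      knots:
      - - 40.0
        - 1.0
      - - 50.0
        - 0.0
    - name: 50Plus
      knots:
      - - 40.0
        - 0.0
      - - 50.0
        - 1.0
    units: years
  thyroiditis:
    type: binary
    values:
    - 'No'
    - 'Yes'
  struma:
    type: binary
    values:
    - 'No'
    - 'Yes'
  nodule_mm:
    type: fuzzy
    universe:
    - 0.0
    - 80.0
    crisp_threshold: 20.0
    sets:
    - name: SmallNodule
      knots:
      - - 10.0
        - 1.0
      - - 20.0
        - 0.0
    - name: LargeNodule
      knots:
      - - 10.0
        - 0.0
      - - 20.0
        - 1.0
    units: mm
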