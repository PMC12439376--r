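# Synthetic template configuration: feature order and types follow the
# published case-study schema; fuzzy knots are illustrative placeholders
# (expert-supplied shapes should replace them before clinical use).
feature_order:
- age
- diabetes
- creatinine
- hemoglobin
- gfr_stage
- proteinuria
- phosphate
- potassium
target: target
positive_class: '1'
negative_class: '0'
threshold: 0.5
variables:
  age:
    type: fuzzy
    universe:
    - 18.0
    - 95.0
    crisp_threshold: 65.0
    sets:
    - name: Elderly
      knots:
      - - 55.0
        - 0.0
      - - 75.0
        - 1.0
    - name: NotElderly
      knots:
      - - 55.0
        - 1.0
      - - 75.0
        - 0.0
    units: years
  diabetes:
    type: binary
    values:
    - 'No'
    - 'Yes'
  creatinine:
    type: fuzzy
    universe:
    - 0.4
    - 10.0
    crisp_threshold: 2.5
    sets:
    - name: HighCreatinine
      knots:
      - - 1.5
        - 0.0
      - - 3.5
        - 1.0
    - name: NotHighCreatinine
      knots:
      - - 1.5
        - 1.0
      - - 3.5
        - 0.0
    units: mg/dL
  hemoglobin:
    type: fuzzy
    universe:
    - 5.0
    - 18.0
    crisp_threshold: 12.0
    sets:
    - name: Anemia
      knots:
      - - 10.0
        - 1.0
      - - 13.0
        - 0.0
    - name: NotAnemia
      knots:
      - - 10.0
        - 0.0
      - - 13.0
        - 1.0
    units: g/dL
  gfr_stage:
    type: categorical
    values:
    - G3a
    - G3b
    - G4
    - G5
  proteinuria:
    type: fuzzy
    universe:
    - 0.0
    - 12.0
    crisp_threshold: 1.0
    sets:
    - name: HighProteinuria
      knots:
      - - 0.3
        - 0.0
      - - 1.7
        - 1.0
    - name: NotHighProteinuria
      knots:
      - - 0.3
        - 1.0
      - - 1.7
        - 0.0
    units: g/day
  phosphate:
    type: fuzzy
    universe:
    - 1.0
    - 10.0
    crisp_threshold: 4.5
    sets:
    - name: HighPhosphate
      knots:
      - - 3.5
        - 0.0
      - - 5.5
        - 1.0
    - name: NotHighPhosphate
      knots:
      - - 3.5
        - 1.0
      - - 5.5
        - 0.0
    units: mg/dL
  potassium:
    type: fuzzy
    universe:
    - 2.5
    - 8.0
    crisp_threshold: 5.0
    sets:
    - name: Hyperkalemia
      knots:
      - - 4.5
        - 0.0
      - - 5.5
        - 1.0
    - name: NotHyperkalemia
      knots:
      - - 4.5
        - 1.0
      - - 5.5
        - 0.0
    units: mmol/L
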