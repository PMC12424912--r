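# Example mapping config: clinical export columns -> ClarID subject
# components. UUIDs become small numeric subject IDs by order of first
# appearance; ages in years are binned into the codebook's decade
# age groups; "'--" and empty cells are treated as missing.
entity: subject
columns:
  study: project.project_id
  subject_id: cases.case_id
  condition: cases.disease_type
  sex: demographics.gender
  type: cohort
recodes:
  sex:
    male: Male
    female: Female
  type:
    case: Case
    control: Control
na_values: ["", "NA", "'--"]
id_strategy: uuid_order
age:
  column: demographics.age_at_index
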