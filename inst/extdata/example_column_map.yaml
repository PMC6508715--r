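# Example column map for reading a spreadsheet/CSV export whose columns do
# not use the canonical field names. Each entry maps a canonical field name
# to the source column header.
patients:
  patient_id: "ID"
  age_years: "Age"
  sex: "Sex"
  ecog: "ECOG"
  tumor_site: "Site"
  location: "Location"
  linitis: "Linitis"
  lauren: "Lauren"
  grade: "Grade"
  her2: "HER2"
  ctnm_stage: "cTNM"
  treatment: "Arm"
  dose_intensity: "DoseIntensity"
  ct_n_positive: "cNpos"
  ypt: "ypT"
  ypn: "ypN"
visits:
  patient_id: "ID"
  visit_index: "Visit"
  time_days: "Day"
  clinical_t: "cT"
  clinical_n: "cN"
  response_dv: "DV"
events:
  patient_id: "ID"
  event_type: "Event"
  time_days: "Day"
  observed: "Observed"
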