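# Default 13-feature clinical catalog (reconstructed default, not a
# published table): feature membership, 0-3 base scores, age boosts for
# elderly-typical features seen before age 55, confounder exclusion rules,
# cohort inclusion/exclusion criteria, and laboratory threshold rules.
inclusion:
  age_min: 18
  age_max: 75
cohort_exclusions:
  - palliative_care
  - alcohol_dependency
  - disseminated_cancer
  - blood_cancer
  - chemotherapy
features:
  - feature_id: hypertrophic_cardiomyopathy
    name: Hypertrophic cardiomyopathy
    sign_group: cardiovascular
    base_score: 1
    evidence_terms: [hypertrophic_cardiomyopathy]
    icd10_prefixes: [I42]
  - feature_id: myocardial_infarction
    name: Myocardial infarction
    sign_group: cardiovascular
    base_score: 1
    age_modifier: {age_below: 55, score: 2}
    evidence_terms: [myocardial_infarction]
    icd10_prefixes: [I21, I22]
  - feature_id: arrhythmia
    name: Arrhythmia / conduction abnormality
    sign_group: cardiovascular
    base_score: 1
    evidence_terms: [arrhythmia]
    icd10_prefixes: [I44, I45, I47, I48, I49]
  - feature_id: renal_failure
    name: Renal failure / impairment
    sign_group: kidney
    base_score: 2
    age_modifier: {age_below: 55, score: 3}
    evidence_terms: [renal_failure]
    icd10_prefixes: [N17, N18, N19]
    lab_findings: [reduced_egfr]
    exclusion_conditions:
      - nephropathy
      - amyloidosis
      - sarcoidosis
      - alport_syndrome
      - nephrectomy
      - urolithiasis
      - congenital_renal_defect
  - feature_id: proteinuria
    name: Proteinuria
    sign_group: kidney
    base_score: 1
    evidence_terms: [proteinuria]
    icd10_prefixes: [R80]
    lab_findings: [proteinuria_lab]
  - feature_id: angiokeratoma
    name: Angiokeratoma
    sign_group: skin
    base_score: 3
    evidence_terms: [angiokeratoma]
  - feature_id: hypohidrosis
    name: Hypohidrosis / heat-cold intolerance
    sign_group: skin
    base_score: 2
    evidence_terms: [hypohidrosis]
    icd10_prefixes: [L74]
  - feature_id: stroke
    name: Stroke / TIA
    sign_group: neurological
    base_score: 2
    age_modifier: {age_below: 55, score: 3}
    evidence_terms: [stroke]
    icd10_prefixes: [I63, I64, G45]
    exclusion_conditions: [patent_foramen_ovale, trauma]
  - feature_id: neuropathic_pain
    name: Neuropathic pain / acroparesthesia
    sign_group: neurological
    base_score: 2
    evidence_terms: [acroparesthesia]
    icd10_prefixes: [R20]
  - feature_id: hearing_impairment
    name: Hearing impairment
    sign_group: neurological
    base_score: 1
    age_modifier: {age_below: 55, score: 2}
    evidence_terms: [hearing_loss]
    icd10_prefixes: [H90, H91]
  - feature_id: gastrointestinal_symptoms
    name: Gastrointestinal symptoms
    sign_group: neurological
    base_score: 1
    evidence_terms: [abdominal_pain]
    icd10_prefixes: [K58, K59, R10]
  - feature_id: recurrent_fever
    name: Recurrent fever
    sign_group: neurological
    base_score: 1
    evidence_terms: [recurrent_fever]
    icd10_prefixes: [R50]
  - feature_id: cornea_verticillata
    name: Cornea verticillata / eye fundus lesions
    sign_group: eye
    base_score: 3
    evidence_terms: [cornea_verticillata]
    icd10_prefixes: [H18]
conditions:
  nephropathy:
    terms: [nephropathy]
    icd10_prefixes: [N14]
  amyloidosis:
    terms: [amyloidosis]
    icd10_prefixes: [E85]
  sarcoidosis:
    terms: [sarcoidosis]
    icd10_prefixes: [D86]
  alport_syndrome:
    terms: [alport_syndrome]
    icd10_prefixes: [Q87.8]
  nephrectomy:
    terms: [nephrectomy]
    icd10_prefixes: [Z90.5]
  urolithiasis:
    terms: [urolithiasis]
    icd10_prefixes: [N20]
  congenital_renal_defect:
    terms: [congenital_renal_defect]
    icd10_prefixes: [Q60, Q61]
  patent_foramen_ovale:
    terms: [patent_foramen_ovale]
    icd10_prefixes: [Q21.1]
  trauma:
    terms: [trauma]
    icd10_prefixes: [S06, T07]
  palliative_care:
    terms: [palliative_care]
    icd10_prefixes: [Z51.5]
  alcohol_dependency:
    terms: [alcohol_dependency]
    icd10_prefixes: [F10]
  disseminated_cancer:
    terms: [disseminated_cancer]
    icd10_prefixes: [C80]
  blood_cancer:
    terms: [blood_cancer]
    icd10_prefixes: [C90, C91, C92]
  chemotherapy:
    terms: [chemotherapy]
    icd10_prefixes: [Z51.1]
lab_rules:
  - analyte: egfr
    op: "<"
    threshold: 60
    unit: mL/min/1.73m2
    finding: reduced_egfr
  - analyte: urine_protein
    op: ">"
    threshold: 150
    unit: mg/24h
    finding: proteinuria_lab
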