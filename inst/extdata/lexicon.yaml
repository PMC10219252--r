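# Default English screening lexicon.
# Terms cover the 13 clinical features of the default catalog plus the
# confounder conditions used by its exclusion rules. The pipeline is
# language-agnostic: lexicon, lemma rules and negation cues are data.
negation_cues: ["no", "not", "without", "denies", "denied", "never"]
adversative_tokens: [but, however, although, though, yet]
lemma_rules:
  - {suffix: omas, replace: oma, min_length: 5}
  - {suffix: ies, replace: "y", min_length: 5}
  - {suffix: ses, replace: sis, min_length: 6}
  - {suffix: is, replace: is, min_length: 4}
  - {suffix: s, replace: "", min_length: 5}
# common note words that must never be "typo-corrected" into a term
extra_vocabulary:
  - patient
  - patients
  - reports
  - examination
  - revealed
  - documented
  - finding
  - findings
  - assessment
  - confirmed
  - evidence
  - history
  - known
  - prior
  - notes
  - mention
  - routine
  - follow
  - visit
  - completed
  - today
  - vital
  - parameters
  - within
  - normal
  - limits
  - advised
  - continue
  - current
  - medication
  - general
  - condition
  - remains
  - satisfactory
  - vaccination
  - status
  - reviewed
  - updated
  - physical
  - otherwise
  - unremarkable
  - counselled
  - regarding
  - lifestyle
  - nutrition
  - outpatient
  - review
  - scheduled
  - three
  - months
entries:
  # --- clinical feature evidence ---
  - term_id: hypertrophic_cardiomyopathy
    canonical: hypertrophic cardiomyopathy
    synonyms: [cardiomyopathy]
    feature_id: hypertrophic_cardiomyopathy
  - term_id: myocardial_infarction
    canonical: myocardial infarction
    synonyms: [heart attack]
    feature_id: myocardial_infarction
  - term_id: arrhythmia
    canonical: arrhythmia
    synonyms: [atrial fibrillation, conduction abnormality]
    feature_id: arrhythmia
  - term_id: renal_failure
    canonical: renal failure
    synonyms: [kidney failure, renal impairment, chronic kidney disease]
    feature_id: renal_failure
  - term_id: proteinuria
    canonical: proteinuria
    synonyms: [protein in urine, albuminuria]
    feature_id: proteinuria
  - term_id: angiokeratoma
    canonical: angiokeratoma
    synonyms: [cherry angioma]
    feature_id: angiokeratoma
  - term_id: hypohidrosis
    canonical: hypohidrosis
    synonyms: [impaired sweating, heat intolerance, cold intolerance]
    feature_id: hypohidrosis
  - term_id: stroke
    canonical: stroke
    synonyms: [transient ischemic attack, cerebral infarction]
    feature_id: stroke
  - term_id: acroparesthesia
    canonical: acroparesthesia
    synonyms: [neuropathic pain, burning pain]
    feature_id: neuropathic_pain
  - term_id: hearing_loss
    canonical: hearing loss
    synonyms: [hearing impairment, sensorineural hearing loss]
    feature_id: hearing_impairment
  - term_id: abdominal_pain
    canonical: abdominal pain
    synonyms: [chronic diarrhea, recurrent nausea]
    feature_id: gastrointestinal_symptoms
  - term_id: recurrent_fever
    canonical: recurrent fever
    synonyms: [febrile episodes]
    feature_id: recurrent_fever
  - term_id: cornea_verticillata
    canonical: cornea verticillata
    synonyms: [whorl keratopathy, corneal opacity]
    feature_id: cornea_verticillata
  # --- confounder / exclusion condition evidence ---
  - term_id: nephropathy
    canonical: nephropathy
    feature_id: condition
  - term_id: amyloidosis
    canonical: amyloidosis
    feature_id: condition
  - term_id: sarcoidosis
    canonical: sarcoidosis
    feature_id: condition
  - term_id: alport_syndrome
    canonical: alport syndrome
    feature_id: condition
  - term_id: nephrectomy
    canonical: nephrectomy
    feature_id: condition
  - term_id: urolithiasis
    canonical: urolithiasis
    synonyms: [kidney stones]
    feature_id: condition
  - term_id: congenital_renal_defect
    canonical: congenital renal defect
    feature_id: condition
  - term_id: patent_foramen_ovale
    canonical: patent foramen ovale
    synonyms: [pfo]
    feature_id: condition
  - term_id: trauma
    canonical: trauma
    synonyms: [head trauma]
    feature_id: condition
  - term_id: palliative_care
    canonical: palliative care
    feature_id: condition
  - term_id: alcohol_dependency
    canonical: alcohol dependency
    synonyms: [alcohol dependence, alcoholism]
    feature_id: condition
  - term_id: disseminated_cancer
    canonical: disseminated cancer
    synonyms: [metastatic cancer]
    feature_id: condition
  - term_id: blood_cancer
    canonical: blood cancer
    synonyms: [leukemia, lymphoma]
    feature_id: condition
  - term_id: chemotherapy
    canonical: chemotherapy
    feature_id: condition
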