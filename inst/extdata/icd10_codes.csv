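code,description
E75.2,Sphingolipidosis including Fabry disease
I42,Cardiomyopathy
I42.1,Obstructive hypertrophic cardiomyopathy
I42.2,Other hypertrophic cardiomyopathy
I21,Acute myocardial infarction
I22,Subsequent myocardial infarction
I44,Atrioventricular and left bundle-branch block
I45,Other conduction disorders
I47,Paroxysmal tachycardia
I48,Atrial fibrillation and flutter
I49,Other cardiac arrhythmias
N17,Acute renal failure
N18,Chronic kidney disease
N19,Unspecified kidney failure
R80,Isolated proteinuria
L74,Eccrine sweat disorders
L74.4,Anhidrosis
I63,Cerebral infarction
I64,Stroke not specified as haemorrhage or infarction
G45,Transient ischemic attack and related syndromes
R20,Disturbances of skin sensation
H90,Conductive and sensorineural hearing loss
H91,Other hearing loss
K58,Irritable bowel syndrome
K59,Other functional intestinal disorders
R10,Abdominal and pelvic pain
R50,Fever of other and unknown origin
H18,Other disorders of cornea
N14,Drug and heavy-metal-induced nephropathy
E85,Amyloidosis
D86,Sarcoidosis
Q87.8,Alport syndrome
Z90.5,Acquired absence of kidney after nephrectomy
N20,Calculus of kidney and ureter
Q60,Renal agenesis and reduction defects of kidney
Q61,Cystic kidney disease
Q21.1,Atrial septal defect including patent foramen ovale
S06,Intracranial injury
T07,Unspecified multiple injuries
Z51.1,Chemotherapy session for neoplasm
Z51.5,Palliative care
F10,Alcohol dependency syndrome
C80,Malignant neoplasm without specification of site
C90,Multiple myeloma and malignant plasma cell neoplasms
C91,Lymphoid leukemia
C92,Myeloid leukemia
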