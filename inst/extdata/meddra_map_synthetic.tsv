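pt	soc
diarrhoea	Gastrointestinal disorders
nausea	Gastrointestinal disorders
vomiting	Gastrointestinal disorders
stomatitis	Gastrointestinal disorders
enteritis	Gastrointestinal disorders
neutropenia	Blood and lymphatic system disorders
febrile neutropenia	Blood and lymphatic system disorders
anaemia	Blood and lymphatic system disorders
thrombocytopenia	Blood and lymphatic system disorders
leukopenia	Blood and lymphatic system disorders
agranulocytosis	Blood and lymphatic system disorders
neutrophil count decreased	Investigations
blood bilirubin increased	Investigations
interstitial lung disease	Respiratory, thoracic and mediastinal disorders
hiccups	Respiratory, thoracic and mediastinal disorders
epistaxis	Respiratory, thoracic and mediastinal disorders
hepatic failure	Hepatobiliary disorders
dehydration	Metabolism and nutrition disorders
hypomagnesaemia	Metabolism and nutrition disorders
hyperammonaemia	Metabolism and nutrition disorders
sepsis	Infections and infestations
septic shock	Infections and infestations
disease progression	General disorders and administration site conditions
asthenia	General disorders and administration site conditions
fatigue	General disorders and administration site conditions
second primary malignancy	Neoplasms benign, malignant and unspecified (incl cysts and polyps)
myelodysplastic syndrome	Neoplasms benign, malignant and unspecified (incl cysts and polyps)
peripheral neuropathy	Nervous system disorders
peripheral sensory neuropathy	Nervous system disorders
aphasia	Nervous system disorders
dysarthria	Nervous system disorders
cholinergic syndrome	Nervous system disorders
skin toxicity	Skin and subcutaneous tissue disorders
dermatitis acneiform	Skin and subcutaneous tissue disorders
palmar-plantar erythrodysaesthesia syndrome	Skin and subcutaneous tissue disorders
paronychia	Skin and subcutaneous tissue disorders
hypertension	Vascular disorders
proteinuria	Renal and urinary disorders
toxic epidermal necrolysis	Skin and subcutaneous tissue disorders
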