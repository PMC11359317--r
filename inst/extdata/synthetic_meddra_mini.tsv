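verbatim_pt	current_pt	soc
Cytokine release syndrome	Cytokine release syndrome	Immune system disorders
Cytokine storm	Cytokine storm	Immune system disorders
ICANS	Immune effector cell-associated neurotoxicity syndrome	Nervous system disorders
Immune effector cell-associated neurotoxicity syndrome	Immune effector cell-associated neurotoxicity syndrome	Nervous system disorders
Neurotoxicity	Neurotoxicity	Nervous system disorders
Encephalopathy	Encephalopathy	Nervous system disorders
Aphasia	Aphasia	Nervous system disorders
Tremor	Tremor	Nervous system disorders
Intention tremor	Intention tremor	Nervous system disorders
Dystonic tremor	Dystonic tremor	Nervous system disorders
Resting tremor	Resting tremor	Nervous system disorders
Essential tremor	Essential tremor	Nervous system disorders
Action tremor	Action tremor	Nervous system disorders
Postural tremor	Postural tremor	Nervous system disorders
Facial paralysis	Facial paralysis	Nervous system disorders
Facial paresis	Facial paresis	Nervous system disorders
Parkinsonism	Parkinsonism	Nervous system disorders
Headache	Headache	Nervous system disorders
HLH	Haemophagocytic lymphohistiocytosis	Immune system disorders
Haemophagocytic lymphohistiocytosis	Haemophagocytic lymphohistiocytosis	Immune system disorders
Immune effector cell-associated HLH-like syndrome	Immune effector cell-associated HLH-like syndrome	Immune system disorders
Hypogammaglobulinemia	Hypogammaglobulinaemia	Immune system disorders
Hypogammaglobulinaemia	Hypogammaglobulinaemia	Immune system disorders
Graft versus host disease	Graft versus host disease	Immune system disorders
Acute graft versus host disease	Acute graft versus host disease	Immune system disorders
Chronic graft versus host disease	Chronic graft versus host disease	Immune system disorders
Graft versus host disease in liver	Graft versus host disease in liver	Immune system disorders
Graft versus host disease in skin	Graft versus host disease in skin	Immune system disorders
Immunodeficiency	Immunodeficiency	Immune system disorders
Bacterial infection	Bacterial infection	Infections and infestations
Bacterial sepsis	Bacterial sepsis	Infections and infestations
Sepsis	Sepsis	Infections and infestations
Pneumonia bacterial	Pneumonia bacterial	Infections and infestations
Clostridium difficile infection	Clostridium difficile infection	Infections and infestations
Staphylococcal infection	Staphylococcal infection	Infections and infestations
Escherichia infection	Escherichia infection	Infections and infestations
Fungal infection	Fungal infection	Infections and infestations
Fungal sepsis	Fungal sepsis	Infections and infestations
Candida infection	Candida infection	Infections and infestations
Aspergillus infection	Aspergillus infection	Infections and infestations
Pneumocystis jirovecii pneumonia	Pneumocystis jirovecii pneumonia	Infections and infestations
Viral infection	Viral infection	Infections and infestations
Cytomegalovirus infection	Cytomegalovirus infection	Infections and infestations
Herpes zoster	Herpes zoster	Infections and infestations
Epstein-Barr virus infection	Epstein-Barr virus infection	Infections and infestations
COVID-19	COVID-19	Infections and infestations
Influenza	Influenza	Infections and infestations
Respiratory syncytial virus infection	Respiratory syncytial virus infection	Infections and infestations
White blood cell count decreased	White blood cell count decreased	Investigations
Platelet count decreased	Platelet count decreased	Investigations
Neutrophil count decreased	Neutrophil count decreased	Investigations
Haemoglobin decreased	Haemoglobin decreased	Investigations
Serum ferritin increased	Serum ferritin increased	Investigations
Blood fibrinogen decreased	Blood fibrinogen decreased	Investigations
Hypoxia	Hypoxia	Respiratory, thoracic and mediastinal disorders
Tachypnoea	Tachypnoea	Respiratory, thoracic and mediastinal disorders
Dyspnoea	Dyspnoea	Respiratory, thoracic and mediastinal disorders
Respiratory failure	Respiratory failure	Respiratory, thoracic and mediastinal disorders
Acute respiratory failure	Acute respiratory failure	Respiratory, thoracic and mediastinal disorders
Pleural effusion	Pleural effusion	Respiratory, thoracic and mediastinal disorders
Malignant pleural effusion	Malignant pleural effusion	Respiratory, thoracic and mediastinal disorders
Atelectasis	Atelectasis	Respiratory, thoracic and mediastinal disorders
Tachycardia	Tachycardia	Cardiac disorders
Sinus tachycardia	Sinus tachycardia	Cardiac disorders
Supraventricular tachycardia	Supraventricular tachycardia	Cardiac disorders
Ventricular tachycardia	Ventricular tachycardia	Cardiac disorders
Arrhythmia	Arrhythmia	Cardiac disorders
Cardiorenal syndrome	Cardiorenal syndrome	Cardiac disorders
Hypotension	Hypotension	Vascular disorders
Capillary leak syndrome	Capillary leak syndrome	Vascular disorders
Orthostatic hypotension	Orthostatic hypotension	Vascular disorders
Shock	Shock	Vascular disorders
Haemorrhagic shock	Haemorrhagic shock	Vascular disorders
Distributive shock	Distributive shock	Vascular disorders
Hypovolaemic shock	Hypovolaemic shock	Vascular disorders
Neurogenic shock	Neurogenic shock	Vascular disorders
Pyrexia	Pyrexia	General disorders
Fatigue	Fatigue	General disorders
Nausea	Nausea	Gastrointestinal disorders
Diarrhoea	Diarrhoea	Gastrointestinal disorders
Rash	Rash	Skin and subcutaneous tissue disorders
Product quality issue	Product quality issue	Product issues
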