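pt	soc
Nausea	Gastrointestinal disorders
Vomiting	Gastrointestinal disorders
Diarrhoea	Gastrointestinal disorders
Diarrhea	Gastrointestinal disorders
Constipation	Gastrointestinal disorders
Abdominal pain upper	Gastrointestinal disorders
Abdominal pain	Gastrointestinal disorders
Abdominal distension	Gastrointestinal disorders
Abdominal discomfort	Gastrointestinal disorders
Eructation	Gastrointestinal disorders
Flatulence	Gastrointestinal disorders
Dyspepsia	Gastrointestinal disorders
Gastrooesophageal reflux disease	Gastrointestinal disorders
Gastrointestinal pain	Gastrointestinal disorders
Pancreatitis	Gastrointestinal disorders
Pancreatitis acute	Gastrointestinal disorders
Pancreatic failure	Gastrointestinal disorders
Diarrhoea haemorrhagic	Gastrointestinal disorders
Hiccups	Respiratory, thoracic and mediastinal disorders
Dysphagia	Gastrointestinal disorders
Gastritis	Gastrointestinal disorders
Ileus	Gastrointestinal disorders
Decreased appetite	Metabolism and nutrition disorders
Dehydration	Metabolism and nutrition disorders
Hypoglycaemia	Metabolism and nutrition disorders
Diabetic ketoacidosis	Metabolism and nutrition disorders
Increased appetite	Metabolism and nutrition disorders
Weight decreased	Investigations
Weight increased	Investigations
Blood glucose increased	Investigations
Blood glucose decreased	Investigations
Hormone level abnormal	Investigations
Lipase increased	Investigations
Amylase increased	Investigations
Headache	Nervous system disorders
Dizziness	Nervous system disorders
Somnolence	Nervous system disorders
Lethargy	Nervous system disorders
Dysgeusia	Nervous system disorders
Syncope	Nervous system disorders
Tremor	Nervous system disorders
Fatigue	General disorders and administration site conditions
Malaise	General disorders and administration site conditions
Asthenia	General disorders and administration site conditions
Drug ineffective	General disorders and administration site conditions
Influenza like illness	General disorders and administration site conditions
Injection site pain	General disorders and administration site conditions
Injection site reaction	General disorders and administration site conditions
Chest discomfort	General disorders and administration site conditions
Pyrexia	General disorders and administration site conditions
Vision blurred	Eye disorders
Visual impairment	Eye disorders
Diabetic retinopathy	Eye disorders
Rash	Skin and subcutaneous tissue disorders
Pruritus	Skin and subcutaneous tissue disorders
Urticaria	Skin and subcutaneous tissue disorders
Alopecia	Skin and subcutaneous tissue disorders
Insomnia	Psychiatric disorders
Anxiety	Psychiatric disorders
Depression	Psychiatric disorders
Suicidal ideation	Psychiatric disorders
Back pain	Musculoskeletal and connective tissue disorders
Myalgia	Musculoskeletal and connective tissue disorders
Arthralgia	Musculoskeletal and connective tissue disorders
Muscle spasms	Musculoskeletal and connective tissue disorders
Dupuytren's contracture	Musculoskeletal and connective tissue disorders
Wrong technique in product usage process	Injury, poisoning and procedural complications
Inappropriate schedule of product administration	Injury, poisoning and procedural complications
Injection site extravasation	Injury, poisoning and procedural complications
Product use in unapproved indication	Injury, poisoning and procedural complications
Accidental overdose	Injury, poisoning and procedural complications
Fall	Injury, poisoning and procedural complications
Fear of injection	Injury, poisoning and procedural complications
Device malfunction	Product issues
Device leakage	Product issues
Needle issue	Product issues
Hepatic pain	Hepatobiliary disorders
Cholelithiasis	Hepatobiliary disorders
Hepatic enzyme increased	Investigations
Acute kidney injury	Renal and urinary disorders
Nephrolithiasis	Renal and urinary disorders
Palpitations	Cardiac disorders
Tachycardia	Cardiac disorders
Heart rate increased	Investigations
Pancreatic carcinoma	Neoplasms benign, malignant and unspecified (incl cysts and polyps)
Thyroid neoplasm	Neoplasms benign, malignant and unspecified (incl cysts and polyps)
Medullary thyroid cancer	Neoplasms benign, malignant and unspecified (incl cysts and polyps)
Hypersensitivity	Immune system disorders
Anaphylactic reaction	Immune system disorders
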