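pt	hlt	hlgt	soc
Deep vein thrombosis	Peripheral embolism and thrombosis	Embolism and thrombosis	Vascular disorders
Deep vein thrombosis postoperative	Peripheral embolism and thrombosis	Embolism and thrombosis	Injury, poisoning and procedural complications
Pulmonary thrombosis	Pulmonary thrombotic and embolic conditions	Pulmonary vascular disorders	Respiratory, thoracic and mediastinal disorders
Pulmonary artery thrombosis	Pulmonary thrombotic and embolic conditions	Pulmonary vascular disorders	Respiratory, thoracic and mediastinal disorders
Cerebral thrombosis	Central nervous system haemorrhages and cerebrovascular accidents	Central nervous system vascular disorders	Nervous system disorders
Cerebral artery thrombosis	Central nervous system haemorrhages and cerebrovascular accidents	Central nervous system vascular disorders	Nervous system disorders
Cerebral venous thrombosis	Central nervous system venous thrombotic conditions	Central nervous system vascular disorders	Nervous system disorders
Cerebral venous sinus thrombosis	Central nervous system venous thrombotic conditions	Central nervous system vascular disorders	Nervous system disorders
Transverse sinus thrombosis	Central nervous system venous thrombotic conditions	Central nervous system vascular disorders	Nervous system disorders
Postoperative thrombosis	Non-site specific procedural complications	Procedural related injuries and complications NEC	Injury, poisoning and procedural complications
Postpartum thrombosis	Maternal complications of delivery	Pregnancy, labour, delivery and postpartum conditions	Pregnancy, puerperium and perinatal conditions
Hepatic vascular thrombosis	Hepatic vascular disorders	Hepatic and hepatobiliary disorders	Hepatobiliary disorders
Portal vein thrombosis	Hepatic vascular disorders	Hepatic and hepatobiliary disorders	Hepatobiliary disorders
Haemorrhoids thrombosed	Haemorrhoids and gastrointestinal varices	Gastrointestinal vascular conditions	Gastrointestinal disorders
Injection site thrombosis	Injection site reactions	Administration site reactions	General disorders and administration site conditions
Application site thrombosis	Application site reactions	Administration site reactions	General disorders and administration site conditions
Vaccination site thrombosis	Vaccination site reactions	Administration site reactions	General disorders and administration site conditions
Ophthalmic vein thrombosis	Ocular vascular disorders	Ocular haemorrhages and vascular disorders	Eye disorders
Ophthalmic artery thrombosis	Ocular vascular disorders	Ocular haemorrhages and vascular disorders	Eye disorders
Ophthalmic vascular thrombosis	Ocular vascular disorders	Ocular haemorrhages and vascular disorders	Eye disorders
Retinal vein thrombosis	Retinal vascular disorders	Ocular haemorrhages and vascular disorders	Eye disorders
Retinal vascular thrombosis	Retinal vascular disorders	Ocular haemorrhages and vascular disorders	Eye disorders
Renal vascular thrombosis	Renal vascular and ischaemic conditions	Renal disorders	Renal and urinary disorders
Splenic thrombosis	Splenic vascular disorders	Spleen, lymphatic and reticuloendothelial system disorders	Blood and lymphatic system disorders
Splenic vein thrombosis	Splenic vascular disorders	Spleen, lymphatic and reticuloendothelial system disorders	Blood and lymphatic system disorders
Vascular pseudoaneurysm thrombosis	Aneurysms and dissections non-site specific	Aneurysms and artery dissections	Vascular disorders
Thrombosis with thrombocytopenia syndrome	Thrombocytopenias	Platelet disorders	Blood and lymphatic system disorders
Pseudothrombophlebitis	Peripheral vascular disorders NEC	Vascular disorders NEC	Vascular disorders
Thrombophlebitis	Phlebitis and thrombophlebitis	Embolism and thrombosis	Vascular disorders
Shunt thrombosis	Medical device complications	Device issues	Injury, poisoning and procedural complications
Thrombosis in device	Medical device complications	Device issues	Injury, poisoning and procedural complications
Vascular graft thrombosis	Medical device complications	Device issues	Injury, poisoning and procedural complications
Infective thrombosis	Infections NEC	Infections - pathogen unspecified	Infections and infestations
Thrombosis	Non-site specific embolism and thrombosis	Embolism and thrombosis	Vascular disorders
Arterial thrombosis	Non-site specific embolism and thrombosis	Embolism and thrombosis	Vascular disorders
Venous thrombosis	Non-site specific embolism and thrombosis	Embolism and thrombosis	Vascular disorders
Venous thrombosis limb	Peripheral embolism and thrombosis	Embolism and thrombosis	Vascular disorders
Superficial vein thrombosis	Peripheral embolism and thrombosis	Embolism and thrombosis	Vascular disorders
Peripheral artery thrombosis	Peripheral embolism and thrombosis	Embolism and thrombosis	Vascular disorders
Subclavian artery thrombosis	Peripheral embolism and thrombosis	Embolism and thrombosis	Vascular disorders
Brachiocephalic vein thrombosis	Peripheral embolism and thrombosis	Embolism and thrombosis	Vascular disorders
Axillary vein thrombosis	Peripheral embolism and thrombosis	Embolism and thrombosis	Vascular disorders
Carotid artery thrombosis	Carotid arterial disorders	Arteriosclerosis, stenosis, vascular insufficiency and necrosis	Vascular disorders
Pelvic venous thrombosis	Pelvic venous disorders	Embolism and thrombosis	Vascular disorders
Intracardiac thrombus	Cardiac disorders NEC	Cardiac disorder signs and symptoms	Cardiac disorders
Thrombosis mesenteric vessel	Gastrointestinal vascular occlusion and infarction	Gastrointestinal vascular conditions	Gastrointestinal disorders
Mesenteric vein thrombosis	Gastrointestinal vascular occlusion and infarction	Gastrointestinal vascular conditions	Gastrointestinal disorders
Headache	Headaches NEC	Headaches	Nervous system disorders
Nausea	Nausea and vomiting symptoms	Gastrointestinal signs and symptoms	Gastrointestinal disorders
Vomiting	Nausea and vomiting symptoms	Gastrointestinal signs and symptoms	Gastrointestinal disorders
Diarrhoea	Diarrhoea	Gastrointestinal motility and defaecation conditions	Gastrointestinal disorders
Abdominal pain	Gastrointestinal and abdominal pains	Gastrointestinal signs and symptoms	Gastrointestinal disorders
Arthralgia	Joint related signs and symptoms	Joint disorders	Musculoskeletal and connective tissue disorders
Injection site pain	Injection site reactions	Administration site reactions	General disorders and administration site conditions
Pyrexia	Febrile disorders	Body temperature conditions	General disorders and administration site conditions
Fatigue	Asthenic conditions	General system disorders NEC	General disorders and administration site conditions
Rash	Rashes, eruptions and exanthems NEC	Epidermal and dermal conditions	Skin and subcutaneous tissue disorders
Pruritus	Pruritus NEC	Epidermal and dermal conditions	Skin and subcutaneous tissue disorders
Infection	Infections NEC	Infections - pathogen unspecified	Infections and infestations
Pneumonia	Lower respiratory tract infections	Infections - pathogen unspecified	Infections and infestations
Dizziness	Neurological signs and symptoms NEC	Neurological disorders NEC	Nervous system disorders
Cough	Coughing and associated symptoms	Respiratory disorder signs and symptoms	Respiratory, thoracic and mediastinal disorders
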