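hlt	soc
Parenchymal lung disorders NEC	Respiratory, thoracic and mediastinal disorders
Pneumothorax and pleural effusions NEC	Respiratory, thoracic and mediastinal disorders
Lower respiratory tract inflammatory and immunologic conditions	Respiratory, thoracic and mediastinal disorders
Respiratory tract disorders NEC	Respiratory, thoracic and mediastinal disorders
Breathing abnormalities	Respiratory, thoracic and mediastinal disorders
Lower respiratory tract signs and symptoms	Respiratory, thoracic and mediastinal disorders
Pulmonary oedemas	Respiratory, thoracic and mediastinal disorders
Respiratory failures (excl neonatal)	Respiratory, thoracic and mediastinal disorders
Vascular pulmonary disorders NEC	Respiratory, thoracic and mediastinal disorders
Bronchospasm and obstruction	Respiratory, thoracic and mediastinal disorders
Coughing and associated symptoms	Respiratory, thoracic and mediastinal disorders
Respiratory syncytial viral infections	Infections and infestations
Bronchial conditions NEC	Respiratory, thoracic and mediastinal disorders
Pulmonary thrombotic and embolic conditions	Respiratory, thoracic and mediastinal disorders
Lower respiratory tract infections NEC	Respiratory, thoracic and mediastinal disorders
Fungal lower respiratory tract infections	Respiratory, thoracic and mediastinal disorders
Pleural infections and inflammations	Respiratory, thoracic and mediastinal disorders
Pleural conditions NEC	Respiratory, thoracic and mediastinal disorders
Respiratory signs and symptoms NEC	Respiratory, thoracic and mediastinal disorders
Laryngeal and adjacent sites disorders NEC	Respiratory, thoracic and mediastinal disorders
Nasal congestion and inflammations	Respiratory, thoracic and mediastinal disorders
Upper respiratory tract infections NEC	Respiratory, thoracic and mediastinal disorders
Tracheobronchial disorders NEC	Respiratory, thoracic and mediastinal disorders
Occupational parenchymal lung disorders	Respiratory, thoracic and mediastinal disorders
Sleep apnoea syndromes	Respiratory, thoracic and mediastinal disorders
Coronavirus infections	Infections and infestations
Conditions associated with abnormal gas exchange	Respiratory, thoracic and mediastinal disorders
Neonatal hypoxic conditions	Respiratory, thoracic and mediastinal disorders
Newborn respiratory disorders NEC	Respiratory, thoracic and mediastinal disorders
Pulmonary hypertensions	Respiratory, thoracic and mediastinal disorders
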