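index	hlt
1	Parenchymal lung disorders NEC
2	Pneumothorax and pleural effusions NEC
3	Lower respiratory tract inflammatory and immunologic conditions
4	Respiratory tract disorders NEC
5	Breathing abnormalities
6	Lower respiratory tract signs and symptoms
7	Pulmonary oedemas
8	Respiratory failures (excl neonatal)
9	Vascular pulmonary disorders NEC
10	Bronchospasm and obstruction
11	Coughing and associated symptoms
12	Respiratory syncytial viral infections
13	Bronchial conditions NEC
14	Pulmonary thrombotic and embolic conditions
15	Lower respiratory tract infections NEC
16	Fungal lower respiratory tract infections
17	Pleural infections and inflammations
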