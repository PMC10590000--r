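icd10_code	combined_code	description
A00	A00	bacterial intestinal infections
A01	A00	bacterial intestinal infections
A03	A00	bacterial intestinal infections
A08	A09	infectious gastroenteritis and colitis
A09	A09	infectious gastroenteritis and colitis
A40	A41	sepsis
A41	A41	sepsis
B96	B96	bacterial infectious agents
C18	C18	colon cancer
C19	C18	colon cancer
C50	C50	breast cancer
D12	D12	benign tumours of colon
D50	D50	iron deficiency anaemia
E03	E03	hypothyroidism
E11	E11	diabetes mellitus
E14	E11	diabetes mellitus
E66	E66	obesity
E78	E78	lipoprotein metabolism disorders
E86	E87	fluid electrolyte and acid-base disorders
E87	E87	fluid electrolyte and acid-base disorders
F17	F17	tobacco abuse
F32	F32	depression
F33	F32	depression
G47	G47	sleep disorders
I10	I10	hypertension
I15	I10	hypertension
I20	I20	angina pectoris
I21	I21	acute myocardial infarction
I22	I21	acute myocardial infarction
I25	I25	chronic ischaemic heart disease
I48	I48	atrial fibrillation and flutter
I50	I50	heart failure
J12	J18	pneumonia
J15	J18	pneumonia
J18	J18	pneumonia
J43	J44	chronic obstructive pulmonary disease
J44	J44	chronic obstructive pulmonary disease
J45	J45	asthma
J46	J45	asthma
J96	J96	respiratory failure
K29	K29	gastritis and duodenitis
K57	K57	diverticular disease of intestine
K59	K59	functional intestinal disorders
K70	K70	alcoholic liver disease
K75	K76	other diseases of liver
K76	K76	other diseases of liver
K80	K80	cholelithiasis
L40	L40	psoriasis
M10	M10	gout
M13	M13	inflammatory arthritis
N17	N17	acute renal failure
N18	N18	chronic kidney disease
N19	N18	chronic kidney disease
T81	T81	complications of procedures
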