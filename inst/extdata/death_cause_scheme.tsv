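chapter_prefix	cause_category	description
A	infectious_parasitic	certain infectious and parasitic diseases
B	infectious_parasitic	certain infectious and parasitic diseases
C	malignant_neoplasms	malignant neoplasms
D	blood_immune	diseases of blood, blood-forming organs, benign/in-situ neoplasms
E	endocrine	endocrine, nutritional and metabolic diseases
F	mental_behavioural	mental and behavioural disorders
G	nervous_system	diseases of the nervous system
H	eye_ear	diseases of the eye, adnexa, ear and mastoid process
I	cardiovascular	diseases of the circulatory system
J	respiratory	diseases of the respiratory system
K	digestive	diseases of the digestive system
L	skin	diseases of the skin and subcutaneous tissue
M	musculoskeletal	diseases of the musculoskeletal system and connective tissue
N	genitourinary	diseases of the genitourinary system
P	congenital_perinatal	perinatal conditions and congenital malformations
Q	congenital_perinatal	perinatal conditions and congenital malformations
R	illdefined	symptoms, signs and ill-defined conditions
S	external	external causes and unnatural death
T	external	external causes and unnatural death
V	external	external causes and unnatural death
W	external	external causes and unnatural death
X	external	external causes and unnatural death
Y	external	external causes and unnatural death
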