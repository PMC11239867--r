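chapter,first,last,name
A00-B99,A00,B99,Certain infectious and parasitic diseases
C00-D48,C00,D48,Neoplasms
D50-D89,D50,D89,Diseases of the blood and blood-forming organs
E00-E90,E00,E90,"Endocrine, nutritional and metabolic diseases"
F00-F99,F00,F99,Mental and behavioural disorders
G00-G99,G00,G99,Diseases of the nervous system
H00-H59,H00,H59,Diseases of the eye and adnexa
H60-H95,H60,H95,Diseases of the ear and mastoid process
I00-I99,I00,I99,Diseases of the circulatory system
J00-J99,J00,J99,Diseases of the respiratory system
K00-K93,K00,K93,Diseases of the digestive system
L00-L99,L00,L99,Diseases of the skin and subcutaneous tissue
M00-M99,M00,M99,Diseases of the musculoskeletal system and connective tissue
N00-N99,N00,N99,Diseases of the genitourinary system
O00-O99,O00,O99,"Pregnancy, childbirth and the puerperium"
U00-U49,U00,U49,Codes for special purposes / emergency use
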