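icd10_pattern,age_min,age_max,frac_preventable,frac_treatable,cause_group
A00-A09,0,74,0,1,infectious
A15-A19,0,74,0.5,0.5,infectious
A35-A37,0,74,1,0,infectious
A39-A41,0,74,0,1,infectious
A80,0,74,1,0,infectious
B05-B06,0,74,1,0,infectious
B15-B19,0,74,0.5,0.5,infectious
B20-B24,0,74,1,0,infectious
G00-G03,0,74,0,1,infectious
J09-J11,0,74,1,0,infectious
C00-C14,0,74,1,0,cancer
C15,0,74,1,0,cancer
C16,0,74,0.5,0.5,cancer
C18-C21,0,74,0.5,0.5,cancer
C22,0,74,1,0,cancer
C33-C34,0,74,1,0,cancer
C43-C44,0,74,1,0,cancer
C50,0,74,0,1,cancer
C53,0,74,0.5,0.5,cancer
C54-C55,0,74,0,1,cancer
C62,0,74,0,1,cancer
C67,0,74,0.5,0.5,cancer
C73,0,74,0,1,cancer
C81,0,74,0,1,cancer
C91-C95,0,44,0,1,cancer
D50-D53,0,74,0,1,other_avoidable
E00-E07,0,74,0,1,diabetes_endocrine
E10-E14,0,74,0.5,0.5,diabetes_endocrine
F10-F16,0,74,1,0,alcohol_drug
F18-F19,0,74,1,0,alcohol_drug
G40-G41,0,74,0,1,other_avoidable
I05-I09,0,74,0,1,other_circulatory
I10-I15,0,74,0.5,0.5,other_circulatory
I20-I25,0,74,0.5,0.5,cardiovascular
I26,0,74,0,1,other_circulatory
I60-I69,0,74,0.5,0.5,cerebrovascular
I71,0,74,0,1,other_circulatory
J12-J18,0,74,0,1,respiratory
J20-J22,0,74,0,1,respiratory
J40-J44,0,74,1,0,respiratory
J45-J46,0,74,0,1,respiratory
J60-J64,0,74,1,0,respiratory
K25-K28,0,74,0,1,digestive
K35-K38,0,74,0,1,digestive
K40-K46,0,74,0,1,digestive
K70,0,74,1,0,alcohol_drug
K80-K81,0,74,0,1,digestive
N00-N07,0,74,0,1,genitourinary
N17-N19,0,74,0,1,genitourinary
N40,0,74,0,1,genitourinary
O00-O99,0,74,0,1,maternal_perinatal
P00-P96,0,0,0,1,maternal_perinatal
Q00-Q99,0,74,0,1,congenital
V01-V99,0,74,1,0,injuries
W00-W19,0,74,1,0,injuries
W65-W74,0,74,1,0,injuries
X00-X09,0,74,1,0,injuries
X40-X49,0,74,1,0,alcohol_drug
X60-X84,0,74,1,0,injuries
X85-Y09,0,74,1,0,injuries
Y10-Y34,0,74,1,0,injuries
Y60-Y69,0,74,0,1,other_avoidable
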