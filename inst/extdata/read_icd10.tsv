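read_code	icd10
G30..	I219
G30z.	I219
G30X.	I213
G30X0	I213
G3071	I214
G301.	I211
G33..	I209
G34z.	I251
G20..	I10X
G575.	I469
G580.	I500
G581.	I501
G58z.	I509
G573.	I489
G66..	I64X
G64z.	I639
G640.	I630
G61..	I619
B34..	C509
B340.	C500
B22z.	C349
B46..	C61X
B7...	D489
H26..	J189
H25..	J180
H3z..	J449
H33..	J459
E012.	F03X
C10..	E149
K190.	N390
A....	B99X
R065.	R074
R023.	R609
R0062	R509
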