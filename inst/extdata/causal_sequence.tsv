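cause_icd10_prefix	consequence_icd10_prefix
I21	I50
I21	I46
I25	I50
I25	I21
I10	I21
I10	I60
I63	J18
C34	J18
C50	J18
C61	J18
C00	R54
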