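source	target
heart attack	myocardial infarction
mi	myocardial infarction
bp	blood pressure
sob	breathlessness
shortness of breath	breathlessness
uti	urinary tract infection
dm	diabetes mellitus
af	atrial fibrillation
cva	stroke
lvf	left ventricular failure
angio	coronary angiogram
ccf	congestive heart failure
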