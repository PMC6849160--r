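code	term
G30..00	myocardial infarction
G30z.00	acute myocardial infarction nos
G30X.00	acute st segment elevation myocardial infarction
G30X000	stemi
G307100	acute non-st segment elevation myocardial infarction
G307111	nstemi
G301.00	acute anterior myocardial infarction
G33..00	angina pectoris
G34z.00	chronic ischaemic heart disease
G20..00	essential hypertension
G575.00	cardiac arrest
G580.00	congestive heart failure
G581.00	left ventricular failure
G581.13	impaired left ventricular function
G58z.00	heart failure
G573.00	atrial fibrillation
G66..00	stroke
G64z.00	cerebral infarction nos
G640.00	cerebral thrombosis
G61..00	intracerebral haemorrhage
B34..00	carcinoma of breast
B340.00	carcinoma of nipple
B22z.00	carcinoma of bronchus
B46..00	carcinoma of prostate
B7...00	neoplasm of uncertain behaviour
H26..00	pneumonia
H25..00	bronchopneumonia
H3z..00	chronic obstructive airways disease
H33..00	asthma
E012.00	senile dementia
C10..00	diabetes mellitus
K190.00	urinary tract infection
A....00	infectious disease
R065.00	chest pain
R023.00	oedema
R006200	fever
182..00	chest pain
173..00	breathlessness
1M...00	pain
199..00	vomiting
2I18.12	tenderness
2C2..11	anaemic
2432.00	irregular pulse
8H3Z.00	other hospital admission nos
8H...00	referral for further care
8HA..11	discharged from follow up
9B0..00	cause of death
242..00	pulse
246..00	blood pressure
3887.00	coronary angiogram
42Z7.00	red blood cell distribution width
42M..00	lymphocyte count
42N..00	monocyte count
42K..00	eosinophil count
42J..00	neutrophil count
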