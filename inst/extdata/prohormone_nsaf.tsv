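id	protein	mean_total	sd_total
CGA	Chromogranin A	98.5	16.0
CGB	Chromogranin B	56.3	2.0
PENK	Proenkephalin	1.5	0.5
NPY	Pro-Neuropeptide Y	7.4	2.2
PCSK1	Prohormone convertase 1 (PC1/3)	4.42	0.8
PCSK2	Prohormone convertase 2 (PC2)	13.8	1.5
PCSK1N	ProSAAS (inhibitor of PC1/3)	15.7	3.9
SCG5	7B2 (regulator of PC2)	4.3	0.9
CPE	Carboxypeptidase E (CPE)	26.7	3.2
PAM	Peptidylglycine alpha-amidating monooxygenase	3.3	1.5
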