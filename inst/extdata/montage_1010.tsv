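electrode	x	y	region	role
F3	-0.35	0.45	frontal	ipsilateral
F5	-0.52	0.48	frontal	ipsilateral
F4	0.35	0.45	frontal	contralateral
F6	0.52	0.48	frontal	contralateral
C3	-0.38	0.00	parietal	ipsilateral
C5	-0.57	0.00	parietal	ipsilateral
CP1	-0.19	-0.23	parietal	ipsilateral
C4	0.38	0.00	parietal	contralateral
C6	0.57	0.00	parietal	contralateral
CP2	0.19	-0.23	parietal	contralateral
CP5	-0.55	-0.25	temporal	ipsilateral
CP3	-0.37	-0.24	temporal	ipsilateral
FC5	-0.55	0.25	temporal	ipsilateral
CP6	0.55	-0.25	temporal	contralateral
CP4	0.37	-0.24	temporal	contralateral
FC6	0.55	0.25	temporal	contralateral
O1	-0.27	-0.76	occipital	ipsilateral
PO3	-0.29	-0.60	occipital	ipsilateral
O2	0.27	-0.76	occipital	contralateral
PO4	0.29	-0.60	occipital	contralateral
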