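synonym	norm_name
COX1	COX1
COXI	COX1
COI	COX1
CO1	COX1
MTCO1	COX1
CYTOCHROMECOXIDASESUBUNIT1	COX1
CYTOCHROMECOXIDASESUBUNITI	COX1
CYTOCHROMEOXIDASESUBUNIT1	COX1
CYTOCHROMEOXIDASESUBUNITI	COX1
COX2	COX2
COXII	COX2
COII	COX2
CO2	COX2
MTCO2	COX2
CYTOCHROMECOXIDASESUBUNIT2	COX2
CYTOCHROMECOXIDASESUBUNITII	COX2
CYTOCHROMEOXIDASESUBUNIT2	COX2
CYTOCHROMEOXIDASESUBUNITII	COX2
COX3	COX3
COXIII	COX3
COIII	COX3
CO3	COX3
MTCO3	COX3
CYTOCHROMECOXIDASESUBUNIT3	COX3
CYTOCHROMECOXIDASESUBUNITIII	COX3
CYTOCHROMEOXIDASESUBUNIT3	COX3
CYTOCHROMEOXIDASESUBUNITIII	COX3
CYTB	CYTB
COB	CYTB
CYB	CYTB
MTCYB	CYTB
CYTOCHROMEB	CYTB
NAD1	NAD1
ND1	NAD1
NADH1	NAD1
NADHDEHYDROGENASESUBUNIT1	NAD1
NAD2	NAD2
ND2	NAD2
NADH2	NAD2
NADHDEHYDROGENASESUBUNIT2	NAD2
NAD3	NAD3
ND3	NAD3
NADH3	NAD3
NADHDEHYDROGENASESUBUNIT3	NAD3
NAD4	NAD4
ND4	NAD4
NADH4	NAD4
NADHDEHYDROGENASESUBUNIT4	NAD4
NAD4L	NAD4L
ND4L	NAD4L
NADH4L	NAD4L
NADHDEHYDROGENASESUBUNIT4L	NAD4L
NAD5	NAD5
ND5	NAD5
NADH5	NAD5
NADHDEHYDROGENASESUBUNIT5	NAD5
NAD6	NAD6
ND6	NAD6
NADH6	NAD6
NADHDEHYDROGENASESUBUNIT6	NAD6
ATP6	ATP6
ATPASE6	ATP6
ATPASE	ATP6
ATP	ATP6
MTATP6	ATP6
ATPSYNTHASEF0SUBUNIT6	ATP6
ATPSYNTHASESUBUNIT6	ATP6
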