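species,b0,b1,b2,b3,b4,b5,use_dbh2,use_cr,use_ba,use_hi,provenance
JP,1.20,0.155,-0.00040,1.00,0.000,0.012,1,1,0,1,package default (Jeffrey pine)
WF,1.00,0.140,-0.00030,1.50,0.000,0.010,1,1,0,1,package default (white fir)
IC,1.10,0.130,-0.00030,1.20,0.000,0.000,1,1,0,0,package default (incense-cedar)
SP,1.30,0.160,-0.00040,0.00,0.000,0.015,1,0,0,1,package default (sugar pine)
LP,0.90,0.120,-0.00030,0.80,0.000,0.000,1,1,0,0,package default (lodgepole pine)
SJ,1.50,0.170,-0.00050,0.00,0.000,0.000,1,0,0,0,package default (western juniper)
QA,0.80,0.110,0.00000,0.00,-0.010,0.000,0,0,1,0,package default (quaking aspen)
QU,1.60,0.180,-0.00050,0.00,-0.012,0.000,1,0,1,0,package default (oak spp.)
PE,0.90,0.120,0.00000,0.00,0.000,0.000,0,0,0,0,package default (bitter cherry)
CONIFER,1.10,0.140,-0.00035,1.00,0.000,0.000,1,1,0,0,package default (conifer fallback)
DEFAULT,1.00,0.130,-0.00030,0.00,0.000,0.000,1,0,0,0,package default (generic fallback)
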