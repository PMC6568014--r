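#NEXUS
BEGIN DATA;
DIMENSIONS NTAX=12 NCHAR=1;
FORMAT SYMBOLS="01" MISSING=? GAP=-;
MATRIX
t1   1
t2   1
t3   0
t4   -
t5   -
t6   -
t7   0
t8   0
t9   -
t10  -
t11  -
t12  -
;
END;
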