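A	-1.32192809488736	-1.32192809488736	-1.32192809488736	1.48542682717024	-1.32192809488736	1.48542682717024
C	-1.32192809488736	-1.32192809488736	-1.32192809488736	-1.32192809488736	1.48542682717024	-1.32192809488736
G	-1.32192809488736	-1.32192809488736	1.48542682717024	-1.32192809488736	-1.32192809488736	-1.32192809488736
T	1.48542682717024	1.48542682717024	-1.32192809488736	-1.32192809488736	-1.32192809488736	-1.32192809488736
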