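base	name	formula	n_C	n_N
A	Adenine	C5H5N5	5	5
G	Guanine	C5H5N5O	5	5
C	Cytosine	C4H5N3O	4	3
T	Thymine	C5H6N2O2	5	2
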