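aa	name	formula	n_C	n_N
A	Alanine	C3H7NO2	3	1
R	Arginine	C6H14N4O2	6	4
N	Asparagine	C4H8N2O3	4	2
D	Aspartate	C4H7NO4	4	1
C	Cysteine	C3H7NO2S	3	1
E	Glutamate	C5H9NO4	5	1
Q	Glutamine	C5H10N2O3	5	2
G	Glycine	C2H5NO2	2	1
H	Histidine	C6H9N3O2	6	3
I	Isoleucine	C6H13NO2	6	1
L	Leucine	C6H13NO2	6	1
K	Lysine	C6H14N2O2	6	2
M	Methionine	C5H11NO2S	5	1
F	Phenylalanine	C9H11NO2	9	1
P	Proline	C5H9NO2	5	1
S	Serine	C3H7NO3	3	1
T	Threonine	C4H9NO3	4	1
W	Tryptophan	C11H12N2O2	11	2
Y	Tyrosine	C9H11NO3	9	1
V	Valine	C5H11NO2	5	1
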