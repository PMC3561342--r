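sample_id	group	total_mapped_reads	read_length
Adipose	normal	22623849	32
Brain	normal	8168675	32
Breast	normal	13605904	32
Colon	normal	22696019	32
Heart	normal	17057207	32
Liver	normal	30654338	32
Lymph Node	normal	23063505	32
Muscle	normal	132812008	32
Testis	normal	24157076	32
BT474	cancer	15406197	32
T47D	cancer	13871105	32
MB435	cancer	16301833	32
MCF7	cancer	13963854	32
Cerebral Cortex	normal	26327918	32
Lung	normal	21650253	32
Kidney	normal	14568451	36
Lymphoma	cancer	2493234	27
DLD-1	cancer	4542765	36
HepG2	cancer	13646471	33
K562	cancer	21778871	33
GM12878	cancer	16451652	33
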