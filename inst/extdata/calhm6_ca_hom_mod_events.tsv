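parent	child	event	count
n2	n3	gain	1
n3	n4	duplication	3
n14	n15	duplication	1
n11	salmo	loss	4
n28	n36	loss	5
n20	n22	loss	5
n29	n30	duplication	2
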