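# Synthetic reconstruction of the curated fly retinal-determination seed
# network: signed undirected edges among the 18 fly genes, assembled from
# canonical relationships in the fly eye-specification literature. This is
# a stand-in default input, not a copy of any single published figure.
gene_a	gene_b	sign
toy	ey	+
ey	so	+
ey	eya	+
ey	dac	+
so	eya	+
eya	dac	+
so	dac	+
ey	tsh	+
tsh	hth	+
hth	ey	-
Dpp	ey	+
Dpp	so	+
Dpp	eya	+
wg	ey	-
wg	Dpp	-
hh	Dpp	+
hh	CI	+
CI	ey	+
shf	hh	-
N	ey	+
N	eyg	+
N	ato	-
h	ato	-
hh	ato	+
ato	so	+
optix	ey	+
optix	so	+
oc	ey	+
eyg	ey	+
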