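gene	neuron_cortex	neuron_hipp	neuron_latvent	glia_cortex	glia_hipp	glia_latvent	cb_purkinje	cb_granular	cb_molecular
FABP7	-	-	-	++	+++	++	-	-	++
GNAS	-	-	-	-	-	-	-	-	-
GPX1	+	+	-	++	++	++	++	-	-
HNRNPH2	+++	+++	+++	+++	++	++	++	+++	+++
HRAS	+++	+++	+++	+++	+++	+++	-	+++	+++
PDZD4	++	+	++	+	+	+++	++	-	++
RPL10	+++	+++	+++	+++	++	++	+++	++	+++
TSPAN7	+++	++	++	-	-	-	-	-	-
MAP2	+++	+++	+++	-	-	-	+++	+++	+++
PRKCB	++	++	++	-	-	+	++	+++	++
MEF2C	+++	+++	+++	+++	+++	+++	+++	+	+++
RAPGEF4	+++	++	-	++	+	++	+++	+	++
APC	+	+	++	++	++	++	++	++	+++
DCX	+++	+	+	++	++	++	++	++	+++
RIMS3	+	+	+	-	-	-	+	++	-
ROBO1	++	++	++	+++	++	++	++	++	++
GLO1	++	++	++	++	++	++	-	-	+
DLX2	+++	++	++	+	+	+	++	+	-
CNR1	++	+	+	+++	+++	+++	+	++	+++
PCDH10	++	++	+	+++	+++	+++	+	++	+++
NLGN3	++	+++	+	-	-	-	+++	+++	-
RELN	+	+	+	-	-	-	+	-	-
CADM1	-	-	-	-	-	-	-	+++	-
CDH22	+	-	-	+	+	+	-	++	-
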