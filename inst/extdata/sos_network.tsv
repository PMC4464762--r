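UmuDC	-	ssDNA
SSB	-	ssDNA
ssDNA	+	RecA
UmuDC	-	RecA
SSB	-	RecA
RecA	-	LexA
sigma70	+	LexA
LexA	-	sigma70
sigma70	+	sigma70
LexA	-	UmuDC
sigma70	+	UmuDC
LexA	-	SSB
sigma70	+	SSB
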