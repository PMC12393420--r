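# Cardiomyocyte literature validation suite: direction of change of a
# readout node under a perturbation, as reported in primary literature.
id	perturbation	readout	expected_direction	context	source
v1	KO:DYRK1A	DNA_replication	increase	cardiomyocyte	DYRK1A loss of function induces cardiomyocyte cell-cycle entry
v2	KO:DYRK1A	CycD	increase	cardiomyocyte	DYRK1A phosphorylates cyclin D and targets it for degradation
v3	OE:DYRK1A	DNA_replication	decrease	cardiomyocyte	DYRK1A overexpression decreases cardiomyocyte proliferation
v4	OE:DYRK1A	E2F1	decrease	cardiomyocyte	DYRK1A overexpression reduces transcription of E2F target genes
v5	OE:CDK2	DNA_replication	increase	cardiomyocyte	CDK2 overexpression promotes cardiomyocyte DNA synthesis
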