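NOTCH21_UP	NOTCH target genes expected to be elevated under pathway activation	HES1	HES2	HES4	HES5	HEY1	HEY2	HEYL	NRARP	NOTCH3	MYC	CDK6	CCND1	KIT	DTX1	DTX4	JAG1	LFNG	GATA3	SOX9	PTCRA	CR2
NOTCH21_DOWN	Genes expected to be suppressed under NOTCH pathway activation	LXN	RAPGEF3	TMEM154	LGR6
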