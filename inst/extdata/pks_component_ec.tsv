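component	description	ec_numbers
PksA	Hypothetical protein	3.1.2.6
Hyp2	Hypothetical protein	3.1.2.6
Regulator	TetR family transcriptional regulator C terminal
PksB	MBL fold metallo hydrolase	2.3.1.39
PksC	ACP S malonyltransferase	2.3.1.51
PksD	Acyltransferase domain containing protein	2.3.1.39
PksE	ACP S malonyltransferase	1.3.1.9;1.3.1.10
AcpK	Acyl carrier protein	2.3.3.10
PksF	Polyketide beta ketoacyl ACP synthase	4.2.1.17
PksG	Hydroxymethylglutaryl CoA synthase family	4.2.1.17
PksH	Enoyl CoA hydratase isomerase
PksI	enoyl CoA hydratase isomerase family protein
PksJ	Non ribosomal peptide synthetase
PksL	SDR family NAD(P) dependent oxidoreductase	1.6.5.2
PksM	SDR family NAD(P) dependent oxidoreductase	1.6.5.2
PksN	Non ribosomal peptide synthetase
PksR	Polyketide synthase dehydratase domain	2.1.1.-
PksS	Cytochrome P450	1.14.14.-
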