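>htt_exon1_first90 human huntingtin N-terminal 90 residues (23-Q allele), NCBI-derived canonical sequence
MATLEKLMKAFESLKSFQQQQQQQQQQQQQQQQQQQQQQQPPPPPPPPPPPQLPQPPPQA
QPLLPQPQPPPPPPPPPPGPAVAEEPLHRP
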