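# Catalytic-site sequence motifs per EC group.
# Short literature motifs plus the flexible-gap GST signature.
ec	pattern
1.14.14.1	FxxGxRxCxG
2.5.1.18	SxAI
2.5.1.18	TxAI
2.5.1.18	PxLxD-x(7,10)-SxAIxxYLxxK
3.1.1.1	GxSxG
3.1.1.7	SEDCL
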