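# Read-filtering accounting reported for the original Bactrocera dorsalis
# transcriptome sequencing run (Illumina paired-end, ~90-base reads).
metric	value
raw_reads	26111110
raw_total_length	2349999900
retained_reads	24068046
retained_paired_reads	23105266
retained_single_reads	962780
retained_total_length	2166124140
read_length	90
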