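chrom	arm	start	end
chr1	p	       1	 32000000
chr1	q	32000001	 85000000
chr2	p	       1	 34000000
chr2	q	34000001	 90000000
chr3	p	       1	 36000000
chr3	q	36000001	 95000000
chr4	p	       1	 38000000
chr4	q	38000001	100000000
chr5	p	       1	 40000000
chr5	q	40000001	105000000
chr6	p	       1	 42000000
chr6	q	42000001	110000000
chr7	p	       1	 44000000
chr7	q	44000001	115000000
chr8	p	       1	 46000000
chr8	q	46000001	120000000
chr9	p	       1	 48000000
chr9	q	48000001	125000000
chr10	p	       1	 50000000
chr10	q	50000001	130000000
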