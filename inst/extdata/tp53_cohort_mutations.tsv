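sample_no	splice_site_label	hgvs_c
1	Exon 3+1 (SD), G >A	c.96+1 G>A
2	Exon 5–1 (SA), G >A	c.376–1 G>A
3	Exon 7+1 (SD), G >A	c.782+1 G>A
4	Exon 5–1 (SA), G >A	c.376–1 G>A
5	Exon 9–2 (SA), A >G	c.920–2 A>G
6	Exon 8+1 (SD), G >A	c.919+1 G>A
7	Exon 5–1 (SA), G>T	c.376–1 G>T
8	Exon 8–1 (SA), G >T	c.783–1 G>T
9	Exon 4+5, G >A	c.375+5 G>A
10	Exon 7–2 (SA), A >T	c.673–2 A>T
11	Exon 5+1 (SD), G >A	c.559+1 G>A
12	Exon 6–1 (SA), G >A	c.560–1 G>A
13	Exon 5+1 (SD), del G	c.559+1del1
14	Exon 6–9 (SA), del 14 bp	c.560–9_564del14
15	Exon 7+3, ins 6 bp	c.782+3_782+4ins6
16	Exon 8–2 (SA), A>G	c.783–2 A>G
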