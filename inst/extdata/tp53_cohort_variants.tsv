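sample_no	variant_no	event	frame_printed	ptc_printed	protein_printed
1	I	exon_skipping:3	Yes	Yes	Truncated
2	I	cryptic_acceptor:4:21	No	No	Loss of 7 AAs 5' exon 5
3	I	intron_retention:7	Yes	Yes	Truncated
4	I	cryptic_acceptor:4:21	No	No	Loss of 7 AAs 5' exon 5
5	I	intron_retention:8	No	Yes	Truncated
5	II	exon_skipping:9	Yes	Yes	Truncated
6	I	intron_retention:8	No	Yes	Truncated
6	II	exon_skipping:8	Yes	Yes	Truncated
7	I	cryptic_acceptor:4:21	No	No	Loss of 7 AAs 5' exon 5
8	I	intron_retention:7	Yes	Yes	Truncated
8	II	cryptic_acceptor:7:24	Yes	No	Loss of 9 AA 5' exon 8, disturbed reading frame
9	I	intron_retention:4	No	Yes	Truncated
10	I	intron_retention:6	No	Yes	Truncated
10	II	cryptic_acceptor:6:-49	Yes	Yes	Truncated
11	I	intron_retention:5	Yes	Yes	Truncated
11	II	cryptic_donor:5:-10	Yes	Yes	Truncated
12	I	intron_retention:5	Yes	Yes	Truncated
12	II	exon_skipping:6	Yes	Yes	Truncated
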