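chr1	toy	gene	30000	40000	.	+	.	gene_id "GENE0001";
chr1	toy	exon	30000	30500	.	+	.	gene_id "GENE0001";
chr1	toy	exon	39000	40000	.	+	.	gene_id "GENE0001";
chr2	toy	gene	60000	65000	.	-	.	gene_id "GENE0002";
chr2	toy	exon	60000	65000	.	-	.	gene_id "GENE0002";
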