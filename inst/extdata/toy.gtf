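##gff-version 2
##source-version rtracklayer 1.62.0
##date 2026-10-01
chr1	rtracklayer	transcript	1000	5000	.	+	.	gene_id "gA"; transcript_id "gA"; biotype "coding"
chr1	rtracklayer	exon	1000	2000	.	+	.	gene_id "gA"; transcript_id "gA"; biotype "coding"
chr1	rtracklayer	transcript	1100	1500	.	-	.	gene_id "lncAnti"; transcript_id "lncAnti"; biotype "lncRNA_candidate"
chr1	rtracklayer	exon	1100	1500	.	-	.	gene_id "lncAnti"; transcript_id "lncAnti"; biotype "lncRNA_candidate"
chr1	rtracklayer	transcript	2200	2600	.	+	.	gene_id "lncIntr"; transcript_id "lncIntr"; biotype "lncRNA_candidate"
chr1	rtracklayer	exon	2200	2600	.	+	.	gene_id "lncIntr"; transcript_id "lncIntr"; biotype "lncRNA_candidate"
chr1	rtracklayer	exon	4000	5000	.	+	.	gene_id "gA"; transcript_id "gA"; biotype "coding"
chr1	rtracklayer	transcript	4200	4600	.	+	.	gene_id "lncSens"; transcript_id "lncSens"; biotype "lncRNA_candidate"
chr1	rtracklayer	exon	4200	4600	.	+	.	gene_id "lncSens"; transcript_id "lncSens"; biotype "lncRNA_candidate"
chr1	rtracklayer	transcript	30000	30500	.	+	.	gene_id "lncInter"; transcript_id "lncInter"; biotype "lncRNA_candidate"
chr1	rtracklayer	exon	30000	30500	.	+	.	gene_id "lncInter"; transcript_id "lncInter"; biotype "lncRNA_candidate"
chr1	rtracklayer	transcript	50000	54000	.	-	.	gene_id "gB"; transcript_id "gB"; biotype "coding"
chr1	rtracklayer	exon	50000	54000	.	-	.	gene_id "gB"; transcript_id "gB"; biotype "coding"
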