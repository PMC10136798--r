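chrT	circArch	gene	1	2100	.	+	.	gene_id "gA";
chrT	circArch	transcript	1	2100	.	+	.	gene_id "gA"; transcript_id "gA.t1";
chrT	circArch	exon	1	200	.	+	.	gene_id "gA"; transcript_id "gA.t1"; exon_number "1";
chrT	circArch	exon	701	900	.	+	.	gene_id "gA"; transcript_id "gA.t1"; exon_number "2";
chrT	circArch	exon	1901	2100	.	+	.	gene_id "gA"; transcript_id "gA.t1"; exon_number "3";
chrT	circArch	gene	3001	5400	.	-	.	gene_id "gB";
chrT	circArch	transcript	3001	5400	.	-	.	gene_id "gB"; transcript_id "gB.t1";
chrT	circArch	exon	3001	3200	.	-	.	gene_id "gB"; transcript_id "gB.t1"; exon_number "3";
chrT	circArch	exon	4201	4400	.	-	.	gene_id "gB"; transcript_id "gB.t1"; exon_number "2";
chrT	circArch	exon	5201	5400	.	-	.	gene_id "gB"; transcript_id "gB.t1"; exon_number "1";
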