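gene_id	atg_pos	allele	note
SKC1	418	ALT	reported non-synonymous SNP set of the salt-tolerant donor haplotype
SKC1	551	ALT	reported non-synonymous SNP set of the salt-tolerant donor haplotype
SKC1	994	ALT	reported non-synonymous SNP set of the salt-tolerant donor haplotype
SKC1	1183	ALT	reported non-synonymous SNP set of the salt-tolerant donor haplotype
GS3	1637	A	premature-stop allele of the elite haplotype group
OsHAK21	6	ALT	reported SNP set of the salt-tolerant donor landrace
OsHAK21	807	ALT	reported SNP set of the salt-tolerant donor landrace
OsHAK21	3740	ALT	reported SNP set of the salt-tolerant donor landrace
OsHAK21	3870	ALT	reported SNP set of the salt-tolerant donor landrace
OsHAK21	3889	ALT	reported SNP set of the salt-tolerant donor landrace
OsHAK21	4082	ALT	reported SNP set of the salt-tolerant donor landrace
OsPAO3	3395	ALT	reported SNP set of the elite variety
OsPAO3	3474	ALT	reported SNP set of the elite variety
OsPAO3	3724	ALT	reported SNP set of the elite variety
RST1	1743	ALT	reported SNP set of the elite haplotype
RST1	1830	ALT	reported SNP set of the elite haplotype
RST1	1986	ALT	reported SNP set of the elite haplotype
RST1	2102	ALT	reported SNP set of the elite haplotype
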