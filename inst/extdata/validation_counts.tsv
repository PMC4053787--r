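# Bookkeeping counts for the SNP / small-indel validation campaign (Sequenom,
# pyrosequencing, Sanger) on the 4 B6J + 4 B6N panel, as published.
key	count
assayed_snps	762
assayed_indels	169
eliminated	363
confirmed_coding_snps	34
confirmed_coding_indels	2
confirmed_noncoding_snps	146
confirmed_noncoding_indels	54
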