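# Risk-allele map for the 7-SNP LTL genetic risk score.
# The risk/other alleles and coordinates below are SYNTHETIC PLACEHOLDERS:
# replace them with the effect alleles of the source GWAS before using the
# score on real genotypes.
snps:
- rsid: rs2736100
  risk_allele: A
  other_allele: G
  source: genotyped
  chrom: '1'
  pos: 1000
- rsid: rs2281929
  risk_allele: A
  other_allele: G
  source: genotyped
  chrom: '2'
  pos: 2000
- rsid: rs11125529
  risk_allele: A
  other_allele: G
  source: imputed
  chrom: '3'
  pos: 3000
- rsid: rs10936599
  risk_allele: A
  other_allele: G
  source: imputed
  chrom: '4'
  pos: 4000
- rsid: rs7675998
  risk_allele: A
  other_allele: G
  source: imputed
  chrom: '5'
  pos: 5000
- rsid: rs9420907
  risk_allele: A
  other_allele: G
  source: imputed
  chrom: '6'
  pos: 6000
- rsid: rs8105767
  risk_allele: A
  other_allele: G
  source: imputed
  chrom: '7'
  pos: 7000
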