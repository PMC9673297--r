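Reported summary tables from a published low-coverage-sequencing study of
wool and body-weight traits in an Angora rabbit population, used as inputs
for interval-arithmetic checks:

angora_qtl_ci.tsv      six QTL with 95% confidence-interval bounds (1-based,
                       inclusive), lead-SNP position/alleles/MAF/p-value
angora_snp_classes.tsv exonic SNP counts by functional class
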