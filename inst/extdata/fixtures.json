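{
  "table2": {
    "file": "table2_accuracy.tsv",
    "md5": "091aed795cb8b610c26ab6ae80b937af",
    "description": "Published accuracy-of-variant-calling counts across genomic contexts and variant types in patient samples: per-stratum false negatives (comparator+/assay-), false positives (comparator-/assay+), true positives and true negatives, with the printed PPA (%) and its 95% CI and the printed NPA (%). pool_consistent marks rows whose printed PPA matches the pooled computation TP/(TP+FN) at 2 decimal places; the insertions row does not (pooled 96.15 vs printed 96.20), consistent with per-sample averaging having been used for that row. Counts were parsed from run-together table typography by requiring the pooled PPA to reproduce the printed value and the heterozygous/homozygous partition to sum (18295+11180=29475 TP; 75+1=76 FN). FP counts do not partition cleanly across zygosity or type rows and no downstream check depends on them."
  },
  "table3": {
    "file": "table3_pgx_concordance.tsv",
    "md5": "318fec6710220c2a8cb7558685c07a9d",
    "description": "Published pharmacogenomic star-allele call concordance across sequencing and orthogonal methods in patient samples: per allele/diplotype row, the number of clinical samples and the pooled overall concordance numerator and denominator across methods. The denominators sum to 595 and the numerators to 595 (100% concordance). Per-method cell counts are not reproduced because the extracted table typography is ambiguous for some rows."
  }
}
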