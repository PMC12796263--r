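#!/usr/bin/env Rscript
# Abundance-stability analyses: replicate filtering, normalization,
# treated-vs-untreated correlation, and tRNA fold changes at every
# grouping level.

suppressMessages(library(psiedit))

cfg <- pipeline_config()

## RNA-seq style matrix: filter, normalize, correlate -----------------------
rna <- read_count_matrix("results/sim/rna_counts.tsv")
untreated_cols <- grep("^untreated", colnames(rna$counts), value = TRUE)
treated_cols <- grep("^treated", colnames(rna$counts), value = TRUE)

flt <- replicate_filter(rna$counts[, untreated_cols],
                        threshold = cfg$rep_filter_log2,
                        pseudocount = cfg$pseudocount)
cat(sprintf("replicate filter: %d/%d features retained\n",
            length(flt$retained), nrow(rna$counts)))

keep <- flt$retained
cpm <- normalize_counts(count_matrix(rna$counts[keep, ]), "CPM")
cor_res <- correlate_conditions(cpm$counts[, treated_cols],
                                cpm$counts[, untreated_cols],
                                pseudocount = cfg$pseudocount)
cat(sprintf("expression correlation: r = %.4f, p = %.3g, n = %d\n",
            cor_res$r, cor_res$p_value, cor_res$n))
write.table(cor_res$table, "results/expression_correlation.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

## tRNA matrix: fold changes by transcript / anticodon / isodecoder ----------
trna <- read_count_matrix("results/sim/trna_counts.tsv")
ann <- read.delim("results/sim/trna_annotation.tsv")
tcols <- grep("^treated", colnames(trna$counts), value = TRUE)
ucols <- grep("^untreated", colnames(trna$counts), value = TRUE)

for (level in c("TRNA", "ANTICODON", "ISODECODER")) {
  fc <- trna_group_fold_change(trna, ann, tcols, ucols, level = level,
                               pseudocount = cfg$pseudocount)
  write.table(fc, sprintf("results/trna_fold_%s.tsv", tolower(level)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (level == "ISODECODER") {
    arg <- arg_isoacceptor_report(fc, ann)
    write.table(arg, "results/trna_arg_isoacceptors.tsv",
                sep = "\t", quote = FALSE, row.names = FALSE)
    cat(sprintf("suppressor isodecoder R-TCT-1: %.2f-fold (log2fc %.3f)\n",
                2^fc$log2fc[fc$feature_id == "R-TCT-1"],
                fc$log2fc[fc$feature_id == "R-TCT-1"]))
    cat(sprintf("other Arg isodecoders: max |log2fc| = %.3f\n",
                max(abs(arg$log2fc[arg$feature_id != "R-TCT-1"]))))
  }
}
anti <- read.delim("results/trna_fold_anticodon.tsv")
cat(sprintf("anticodon groups: max |log2fc| outside R-TCT = %.3f\n",
            max(abs(anti$log2fc[anti$feature_id != "R-TCT"]))))
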