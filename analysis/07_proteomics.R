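#!/usr/bin/env Rscript
# Amino-acid incorporation at the premature termination codon from the
# peptide abundance table.

suppressMessages(library(psiedit))

pep <- read_peptide_table("results/sim/peptides.tsv")
res <- incorporation_rate(pep)

tab <- data.frame(residue = names(res$fractions),
                  fraction = as.numeric(res$fractions))
tab <- tab[order(-tab$fraction), ]
write.table(tab, "results/ptc_incorporation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("retained %d peptides (PSM > 1)\n", res$n_retained))
cat(sprintf("dominant residue at the PTC: %s at %.2f%%\n",
            res$dominant, 100 * res$fractions[[res$dominant]]))
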