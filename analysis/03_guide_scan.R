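#!/usr/bin/env Rscript
# Predict candidate off-target loci by guide complementarity, rank the top
# regions, and check the observed site calls at the predicted loci.

suppressMessages(library(psiedit))

tx <- read_fasta("results/sim/transcriptome.fa")
planted <- read.delim("results/sim/planted_guide_windows.tsv")
cfg <- pipeline_config()

matches <- scan_guide_complementarity(tx, "AATTTACTNAACAGAGG", cfg)
top <- rank_top_regions(matches, k = cfg$top_k)
write_guide_matches(top, "results/guide_top_regions.tsv",
                    "results/guide_top_regions.bed")

key <- function(d, s) paste(d$transcript_id, s)
cat(sprintf("scan: %d windows at <= %d mismatches; %d/%d planted recovered\n",
            nrow(matches), cfg$max_mismatches,
            sum(key(planted, planted$start) %in% key(matches, matches$start)),
            nrow(planted)))

# were any predicted loci actually modified? (the planted edited sites are
# placed independently of the planted guide windows, so the expectation is 0)
calls <- read.delim("results/offtarget_calls.tsv")
calls$pos <- calls$pos_1based - 1L
calls$delta_plus_treated <- as.numeric(calls$delta_plus_treated)
pred <- data.frame(transcript_id = top$transcript_id,
                   target_pos = top$target_pos)
chk <- check_predicted_loci(calls, pred)
write.table(chk$table, "results/predicted_loci_check.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("predicted loci: %d checked, %d with an off-target call\n",
            chk$n_predicted, chk$n_called))
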