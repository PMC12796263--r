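#!/usr/bin/env Rscript
# Ribosome-profiling safety readouts: RRTS per transcript, readthrough
# event overlap between conditions, 3'UTR footprint density comparison,
# the stop-codon metagene profile, and translation efficiency.

suppressMessages(library(psiedit))

ann <- read.delim("results/sim/ribo_annotation.tsv")
seqs <- read_fasta("results/sim/ribo_transcripts.fa")
models <- lapply(seq_len(nrow(ann)), function(i)
  transcript_model(ann$transcript_id[i], seqs[[ann$transcript_id[i]]],
                   ann$cds_start[i], ann$cds_end[i]))
cfg <- pipeline_config()

load_tracks <- function(path) {
  df <- read.delim(path)
  lapply(split(df, df$transcript_id), function(d)
    d$count[order(d$pos_1based)])[ann$transcript_id]
}
tr_t <- load_tracks("results/sim/psite_treated.tsv")
tr_u <- load_tracks("results/sim/psite_untreated.tsv")

rr_t <- rrts_table(tr_t, models, cfg)
rr_u <- rrts_table(tr_u, models, cfg)
write.table(rr_t, "results/rrts_treated.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(rr_u, "results/rrts_untreated.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
ev <- compare_readthrough_events(rr_t, rr_u)
cat(sprintf("readthrough events: %d treated, %d untreated, %d shared\n",
            ev$n_a, ev$n_b, ev$n_shared))

utr <- utr3_density_comparison(tr_t, tr_u, models)
write.table(utr$table, "results/utr3_density.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("3'UTR RPF density: median diff %.4f, %.0f%% transcripts increased\n",
            utr$median_diff, 100 * utr$fraction_increased))

prof <- metagene_stop_profile(tr_u, models)
write.table(prof, "results/metagene_stop_untreated.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

rna <- read_count_matrix("results/sim/rna_counts.tsv")
ribo <- read_count_matrix("results/sim/ribo_counts.tsv")
te <- translation_efficiency(rna, ribo, cfg)
write.table(te, "results/translation_efficiency.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("TE: %d/%d genes pass inclusion (%s)\n",
            sum(te$included), nrow(te),
            paste(names(table(te$reason[!te$included])),
                  table(te$reason[!te$included]), collapse = ", ")))
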