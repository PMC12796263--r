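#!/usr/bin/env Rscript
# Generate every synthetic input the downstream analyses consume, with
# planted ground truth, under results/sim/. All later scripts read only
# these files (and the truth tables, for comparison plots/summaries).

suppressMessages(library(psiedit))

seed <- 1L
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## Transcriptome with planted guide-complementary windows -------------------
pattern <- "AATTTACTNAACAGAGG"
sim_tx <- sim_transcriptome(
  n_transcripts = 10, length_range = c(8000, 12000),
  planted_motifs = list(list(pattern = pattern, n_copies = 3, n_mismatches = 0),
                        list(pattern = pattern, n_copies = 3, n_mismatches = 2)),
  seed = seed)
write_fasta(sim_tx$sequences, file.path(out, "transcriptome.fa"))
write.table(sim_tx$truth, file.path(out, "planted_guide_windows.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

## Deletion-signature site counts -------------------------------------------
# 10 planted edited sites (treated-only signal) among 500 null sites, plus
# 30 endogenous sites (signal in both treatments).
sites <- data.frame(
  transcript_id = sample(names(sim_tx$sequences), 540, replace = TRUE),
  pos = sample(100:7900, 540),
  delta_plus_treated = c(rep(0.30, 10), rep(0.02, 500), rep(0.40, 30)),
  delta_plus_untreated = c(rep(0.02, 510), rep(0.40, 30)))
truth_sites <- cbind(sites,
                     class = c(rep("edited", 10), rep("null", 500),
                               rep("endogenous", 30)))
sc <- sim_praise_counts(sites, background_minus = 0.01, depth = 1000,
                        seed = seed + 1L)
write_site_counts(sc, file.path(out, "site_counts.tsv"))
write.table(truth_sites, file.path(out, "site_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

## UMI-tagged amplicon reads -------------------------------------------------
set.seed(seed + 2L)
amplicon_ref <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                      collapse = "")
amp <- sim_amplicon_reads(1000, 3:15, amplicon_ref, per_base_error = 0.01,
                          deletion_fraction_at_target = 0.25,
                          target_pos = 60, seed = seed + 3L)
writeLines(amplicon_ref, file.path(out, "amplicon_reference.txt"))
write.table(amp$reads, file.path(out, "amplicon_reads.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(amp$truth, file.path(out, "amplicon_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

## Ribosome-profiling coverage ------------------------------------------------
make_tx <- function(id, cds_codons, utr_len) {
  cds <- paste(c(rep("ATG", cds_codons - 1), "TAA"), collapse = "")
  utr <- paste(rep("CAC", utr_len / 3), collapse = "")
  transcript_model(id, paste0(cds, utr), 0, 3 * cds_codons)
}
ribo_tx <- c(lapply(sprintf("rt%02d", 1:5), make_tx, cds_codons = 200,
                    utr_len = 300),
             lapply(sprintf("nt%02d", 1:15), make_tx, cds_codons = 200,
                    utr_len = 300))
rt_set <- setNames(rep(0.3, 5), sprintf("rt%02d", 1:5))
cov_treated <- sim_ribo_coverage(ribo_tx, cds_density = 2,
                                 readthrough_set = rt_set, seed = seed + 4L)
cov_untreated <- sim_ribo_coverage(ribo_tx, cds_density = 2, seed = seed + 5L)
saveit <- function(tracks, path) {
  df <- do.call(rbind, lapply(names(tracks), function(tx)
    data.frame(transcript_id = tx, pos_1based = seq_along(tracks[[tx]]),
               count = tracks[[tx]])))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
saveit(cov_treated$tracks, file.path(out, "psite_treated.tsv"))
saveit(cov_untreated$tracks, file.path(out, "psite_untreated.tsv"))
ann <- data.frame(transcript_id = vapply(ribo_tx, `[[`, "", "transcript_id"),
                  length = vapply(ribo_tx, `[[`, 1L, "length"),
                  cds_start = vapply(ribo_tx, `[[`, 1L, "cds_start"),
                  cds_end = vapply(ribo_tx, `[[`, 1L, "cds_end"))
write.table(ann, file.path(out, "ribo_annotation.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_fasta(setNames(vapply(ribo_tx, `[[`, "", "sequence"),
                     ann$transcript_id),
            file.path(out, "ribo_transcripts.fa"))

## RNA-seq and Ribo-seq count matrices for TE ---------------------------------
rna_sim <- sim_count_matrix(500, n_replicates = 2, nb_dispersion = 0.01,
                            base_mean = 300, seed = seed + 6L)
ribo_sim <- sim_count_matrix(500, n_replicates = 2, nb_dispersion = 0.01,
                             base_mean = 40, seed = seed + 7L)
write_count_matrix(rna_sim$cm, file.path(out, "rna_counts.tsv"))
write_count_matrix(ribo_sim$cm, file.path(out, "ribo_counts.tsv"))

## tRNA counts with the planted suppressor ------------------------------------
trna <- sim_trna_matrix(planted_fold = 1.5, seed = seed + 8L)
write_count_matrix(trna$cm, file.path(out, "trna_counts.tsv"))
write.table(trna$annotation, file.path(out, "trna_annotation.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

## Peptide table ---------------------------------------------------------------
pep <- sim_peptide_table(c(R = 0.9998, W = 0.0002), 20000, seed = seed + 9L)
write.table(pep$peptides, file.path(out, "peptides.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("simulated inputs written under", out, "\n")
cat("planted: 10 edited sites, 30 endogenous sites,",
    nrow(sim_tx$truth), "guide windows, 25% amplicon editing,",
    "5 readthrough transcripts (ratio 0.3), 1.5x suppressor tRNA,",
    "99.98% arginine at the PTC\n")
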