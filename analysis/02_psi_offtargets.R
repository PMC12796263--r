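#!/usr/bin/env Rscript
# Site-level pseudouridine analysis: deletion-rate stoichiometry, the
# four-criterion off-target caller, endogenous-site calling in untreated
# samples, and the treated-vs-untreated stoichiometry comparison.

suppressMessages(library(psiedit))

sc <- read_site_counts("results/sim/site_counts.tsv")
truth <- read.delim("results/sim/site_truth.tsv")
cfg <- pipeline_config()
dir.create("results", showWarnings = FALSE)

calls <- call_offtarget_sites(sc, cfg)
write_call_table(calls, "results/offtarget_calls.tsv")
write_bed(with(calls[calls$is_offtarget, ],
               data.frame(transcript_id = transcript_id, start = pos,
                          end = pos + 1L, name = "offtarget",
                          score = round(delta, 3))),
          "results/offtarget_calls.bed")

endo <- call_endogenous_sites(sc, cfg)
write_call_table(endo, "results/endogenous_calls.tsv")

key <- function(d) paste(d$transcript_id, d$pos)
planted_ot <- truth[truth$class == "edited", ]
planted_en <- truth[truth$class == "endogenous", ]
called <- calls[calls$is_offtarget, ]
cat(sprintf("off-target caller: %d called; %d/%d planted recovered; %d false\n",
            nrow(called),
            sum(key(planted_ot) %in% key(called)), nrow(planted_ot),
            sum(!key(called) %in% key(planted_ot))))
cat(sprintf("endogenous caller: %d called; %d/%d planted recovered\n",
            sum(endo$is_endogenous),
            sum(key(planted_en) %in% key(endo[endo$is_endogenous, ])),
            nrow(planted_en)))

# endogenous stoichiometry should be stable across treatment: compare the
# treated vs untreated PRAISE(+) rates at endogenous sites
endo_sites <- endo[endo$is_endogenous, ]
treated_view <- data.frame(transcript_id = calls$transcript_id,
                           pos = calls$pos,
                           delta = calls$delta_plus_treated)
cmp <- compare_stoichiometry(treated_view, endo_sites,
                             threshold = cfg$stoich_shift_threshold)
write.table(cmp$table, "results/stoichiometry_comparison.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("stoichiometry: %d shared endogenous sites, %d shifted by > %.2f\n",
            cmp$n_shared, cmp$n_shifted, cfg$stoich_shift_threshold))
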