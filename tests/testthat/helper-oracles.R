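# Independent oracles and small fixture builders shared across tests.

# Naive O(L*17) sliding-window scan: walks every window with explicit
# character comparisons, independently of the vectorised implementation.
naive_guide_scan <- function(seqs, pattern, max_mm = 3L) {
  pc <- strsplit(pattern, "")[[1]]
  npos <- which(pc == "N")
  tpos <- npos - 1L
  scored <- setdiff(seq_len(17L), c(npos, tpos))
  out <- list()
  for (tx in names(seqs)) {
    ch <- strsplit(seqs[[tx]], "")[[1]]
    L <- length(ch)
    if (L < 17L) next
    for (s in seq_len(L - 16L)) {
      w <- ch[s:(s + 16L)]
      if (w[tpos] != "T") next
      mm <- sum(w[scored] != pc[scored])
      if (mm <= max_mm)
        out[[length(out) + 1L]] <- data.frame(
          transcript_id = tx, start = s - 1L, mismatches = mm,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(transcript_id = character(0), start = integer(0),
                      mismatches = integer(0)))
  do.call(rbind, out)
}

# Single site-count row in the internal layout.
site_row <- function(tx, pos, chem, treat, depth, dels,
                     sample_id = paste0(chem, "_", treat)) {
  data.frame(transcript_id = tx, pos = pos, sample_id = sample_id,
             chemistry = chem, treatment = treat,
             depth = depth, deletions = dels, stringsAsFactors = FALSE)
}

# Four-condition counts for one locus with deterministic deletion counts.
locus_counts <- function(tx, pos, depth, del_pt, del_pu, del_mt, del_mu) {
  rbind(site_row(tx, pos, "PRAISE_PLUS", "TREATED", depth, del_pt),
        site_row(tx, pos, "PRAISE_PLUS", "UNTREATED", depth, del_pu),
        site_row(tx, pos, "PRAISE_MINUS", "TREATED", depth, del_mt),
        site_row(tx, pos, "PRAISE_MINUS", "UNTREATED", depth, del_mu))
}

# Transcript whose 3'UTR is free of in-frame stop codons (poly-CAC), so the
# readthrough region spans the whole 3'UTR.
clean_utr_transcript <- function(id, cds_codons = 100L, utr_len = 90L) {
  cds <- paste(c(rep("ATG", cds_codons - 1L), "TAA"), collapse = "")
  utr <- paste(rep("CAC", utr_len / 3L), collapse = "")
  transcript_model(id, paste0(cds, utr), 0L, 3L * cds_codons)
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")
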