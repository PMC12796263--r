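test_that("P-site assignment applies offsets and drops out-of-range reads", {
  fp <- data.frame(transcript_id = "tx1", pos5 = c(100L, 990L, 10L),
                   length = c(28L, 30L, 20L))
  tracks <- assign_psites(fp, c(tx1 = 1000L))
  expect_equal(which(tracks$tx1 > 0) - 1L, 112L)  # 100 + 12
  # length-20 footprint outside 26:34 and the 990+12 overflow both dropped
  expect_equal(attr(tracks, "dropped"), 2L)

  none <- assign_psites(fp[0, ], c(tx1 = 50L))
  expect_equal(sum(none$tx1), 0L)
  expect_length(none$tx1, 50L)

  per_len <- assign_psites(
    data.frame(transcript_id = "tx1", pos5 = c(0L, 0L), length = c(28L, 29L)),
    c(tx1 = 100L), offset_table = c(`28` = 12, `29` = 13))
  expect_equal(which(per_len$tx1 > 0) - 1L, c(12L, 13L))
})

test_that("RRTS matches closed-form constructions", {
  tm <- clean_utr_transcript("tx1", cds_codons = 100, utr_len = 90)
  # uniform density 0.1: 1 read every 10 nt in CDS and readthrough region
  track <- integer(tm$length)
  track[seq(5, tm$length, by = 10)] <- 1L
  rec <- rrts(track, tm, pipeline_config(rrts_min_cds_reads = 10))
  expect_equal(rec$rrts, 1.0, tolerance = 1e-12)

  # zero readthrough reads
  track2 <- integer(tm$length)
  track2[seq(1, tm$cds_end, by = 5)] <- 1L
  expect_equal(rrts(track2, tm)$rrts, 0)

  # CDS 300 nt / 60 reads, readthrough 90 nt / 3 reads -> (3/90)/(60/300)
  tm3 <- clean_utr_transcript("tx3", cds_codons = 100, utr_len = 90)
  track3 <- integer(tm3$length)
  track3[seq(1, 300, length.out = 60)] <- 1L
  track3[300 + c(10, 40, 80)] <- 1L
  expect_equal(rrts(track3, tm3)$rrts, (3 / 90) / (60 / 300),
               tolerance = 1e-12)
})

test_that("RRTS is undefined without a 3'UTR or adequate CDS coverage", {
  seqs <- paste(c(rep("ATG", 99), "TAA"), collapse = "")
  no_utr <- transcript_model("tx1", seqs, 0, 300)
  track <- rep(1L, 300)
  rec <- rrts(track, no_utr)
  expect_true(is.na(rec$rrts))
  expect_equal(rec$reason, "no_utr3")

  tm <- clean_utr_transcript("tx2")
  low <- integer(tm$length)
  low[c(3, 33)] <- 1L
  rec2 <- rrts(low, tm, pipeline_config(rrts_min_cds_reads = 20))
  expect_true(is.na(rec2$rrts))
  expect_equal(rec2$reason, "low_cds_coverage")
})

test_that("readthrough region stops at the next in-frame stop codon", {
  # CDS then 9 nt, then an in-frame TAA, then more UTR
  seqs <- paste0(paste(c(rep("ATG", 9), "TAA"), collapse = ""),
                 "CACCACCAC", "TAA", "CACCACCACCAC")
  tm <- transcript_model("tx1", seqs, 0, 30)
  track <- rep(1L, tm$length)
  rec <- rrts(track, tm, pipeline_config(rrts_min_cds_reads = 5))
  expect_equal(c(rec$rt_start, rec$rt_end), c(30, 39))
})

test_that("3'UTR density comparison localises planted readthrough", {
  tms <- list(clean_utr_transcript("a", 50, 60),
              clean_utr_transcript("b", 50, 60),
              transcript_model("c", paste(c(rep("ATG", 19), "TAA"),
                                          collapse = ""), 0, 60))
  cov_u <- sim_ribo_coverage(tms, 5, seed = 31)
  same <- utr3_density_comparison(cov_u$tracks, cov_u$tracks, tms)
  expect_true(all(same$table$diff == 0))
  expect_equal(same$n_excluded, 1L)  # transcript c has no 3'UTR

  cov_t <- sim_ribo_coverage(tms, 5, readthrough_set = c(a = 0.5), seed = 32)
  cmp <- utr3_density_comparison(cov_t$tracks, cov_u$tracks, tms)
  expect_gt(cmp$table$diff[cmp$table$transcript_id == "a"], 0)
  expect_equal(cmp$table$density_untreated[cmp$table$transcript_id == "b"],
               cmp$table$density_treated[cmp$table$transcript_id == "b"])
})

test_that("metagene profile is normalized and depth-invariant", {
  tm <- clean_utr_transcript("tx1", cds_codons = 60, utr_len = 60)
  # uniform CDS density 2, nothing downstream
  track <- integer(tm$length)
  track[1:tm$cds_end] <- 2L
  prof <- metagene_stop_profile(list(tx1 = track), list(tm),
                                window = c(30L, 45L))
  up <- prof$mean_density[prof$rel_pos < 0]
  down <- prof$mean_density[prof$rel_pos >= 3]
  expect_true(all(abs(up - 1) < 1e-12))
  expect_true(all(down == 0))

  # second transcript = same shape at 10x depth; profile unchanged
  tm2 <- clean_utr_transcript("tx2", cds_codons = 60, utr_len = 60)
  track2 <- track * 10L
  prof2 <- metagene_stop_profile(list(tx1 = track, tx2 = track2),
                                 list(tm, tm2), window = c(30L, 45L))
  expect_equal(prof2$mean_density, prof$mean_density, tolerance = 1e-12)

  empty <- metagene_stop_profile(list(), list(), window = c(10L, 10L))
  expect_equal(nrow(empty), 0L)
})

test_that("readthrough event comparison is plain set algebra", {
  mk <- function(ids, events) data.frame(transcript_id = ids,
                                         is_event = ids %in% events)
  a <- mk(c("A", "B", "C", "Z"), c("A", "B", "C"))
  b <- mk(c("B", "C", "D", "Z"), c("B", "C", "D"))
  cmp <- compare_readthrough_events(a, b)
  expect_equal(cmp$shared, c("B", "C"))
  expect_equal(cmp$a_only, "A")
  expect_equal(cmp$b_only, "D")
  expect_equal(cmp$n_shared, 2L)

  idem <- compare_readthrough_events(a, a)
  expect_equal(idem$n_shared, idem$n_a)
  none <- compare_readthrough_events(mk("Z", character(0)), b)
  expect_equal(none$b_only, c("B", "C", "D"))
})

test_that("translation efficiency follows the printed ratio and criteria", {
  genes <- c("g1", "g2")
  rna <- count_matrix(matrix(c(100L, 900L, 100L, 900L), 2, 2,
                             dimnames = list(genes, c("r1", "r2"))))
  ribo <- count_matrix(matrix(c(50L, 950L, 50L, 950L), 2, 2,
                              dimnames = list(genes, c("r1", "r2"))))
  te <- translation_efficiency(rna, ribo)
  # g1: RNA CPM 1e5, Ribo CPM 5e4 -> TE 2
  expect_equal(te$te[te$gene_id == "g1"], 2.0, tolerance = 1e-12)

  flipped <- translation_efficiency(rna, ribo,
                                    pipeline_config(te_direction = "ribo_over_rna"))
  expect_equal(flipped$te[flipped$gene_id == "g1"], 0.5, tolerance = 1e-12)

  # ribo count 19 -> excluded with the ribo_count reason
  ribo19 <- count_matrix(matrix(c(19L, 981L, 19L, 981L), 2, 2,
                                dimnames = list(genes, c("r1", "r2"))))
  te19 <- translation_efficiency(rna, ribo19)
  expect_false(te19$included[te19$gene_id == "g1"])
  expect_equal(te19$reason[te19$gene_id == "g1"], "ribo_count")

  # absent in one replicate -> replicate reason
  rna0 <- count_matrix(matrix(c(0L, 1000L, 100L, 900L), 2, 2,
                              dimnames = list(genes, c("r1", "r2"))))
  te0 <- translation_efficiency(rna0, ribo)
  expect_equal(te0$reason[te0$gene_id == "g1"], "replicate")
})

test_that("TE inclusion matches a brute-force filter on random matrices", {
  cfg <- pipeline_config()
  for (s in 1:5) {
    set.seed(s)
    n <- 200L
    genes <- sprintf("g%03d", 1:n)
    rna <- matrix(rpois(n * 2, exp(runif(n * 2, 0, 6))), n, 2,
                  dimnames = list(genes, c("r1", "r2")))
    ribo <- matrix(rpois(n * 2, exp(runif(n * 2, 0, 6))), n, 2,
                   dimnames = list(genes, c("r1", "r2")))
    te <- translation_efficiency(count_matrix(rna), count_matrix(ribo), cfg)
    rna_cpm <- t(t(rna) * 1e6 / colSums(rna))
    brute <- logical(n)
    for (i in 1:n) {
      brute[i] <- all(rna[i, ] > 0) && all(ribo[i, ] > 0) &&
        all(rna_cpm[i, ] >= cfg$te_min_rna_cpm) &&
        min(ribo[i, ]) >= cfg$te_min_ribo_count
    }
    expect_equal(te$included, brute)
  }
})
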