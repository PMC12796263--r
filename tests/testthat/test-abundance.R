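test_that("normalization matches the per-million and per-kb formulas", {
  m <- matrix(c(200L, 999800L), 2, 1,
              dimnames = list(c("gA", "gB"), "s1"))
  cm <- count_matrix(m, feature_lengths = c(gA = 2000, gB = 500))
  rpkm <- normalize_counts(cm, "RPKM")
  expect_equal(rpkm$counts["gA", "s1"], 100)  # 200 reads, 2 kb, 1e6 library

  single <- count_matrix(matrix(42L, 1, 1, dimnames = list("g", "s")))
  expect_equal(normalize_counts(single, "CPM")$counts[1, 1], 1e6)

  eq <- count_matrix(matrix(7L, 5, 2, dimnames = list(paste0("g", 1:5),
                                                      c("a", "b"))))
  cpm <- normalize_counts(eq, "CPM")
  expect_true(all(cpm$counts == 2e5))
  expect_equal(colSums(cpm$counts), c(a = 1e6, b = 1e6))

  expect_error(normalize_counts(cpm, "CPM"), "already normalized")
  expect_error(normalize_counts(count_matrix(
    matrix(c(1L, 0L), 1, 2, dimnames = list("g", c("a", "b")))), "RPM"),
    "zero library size")
  expect_error(normalize_counts(count_matrix(m), "RPKM"), "lengths")
})

test_that("CPM/RPM columns always sum to one million", {
  set.seed(13)
  for (i in 1:10) {
    m <- matrix(rpois(60, exp(runif(60, 0, 8))), 20, 3,
                dimnames = list(sprintf("f%02d", 1:20), c("a", "b", "c")))
    cpm <- normalize_counts(count_matrix(m), sample(c("CPM", "RPM"), 1))
    expect_true(all(abs(colSums(cpm$counts) - 1e6) < 1e-6 * 1e6))
  }
})

test_that("the reproducibility filter removes only divergent replicates", {
  m <- matrix(c(100L, 40L, 15L, 100L, 10L, 10L), 3, 2,
              dimnames = list(c("same", "fourfold", "mild"), c("r1", "r2")))
  res <- replicate_filter(count_matrix(m), threshold = 1, pseudocount = 0.5)
  expect_true("same" %in% res$retained)       # equal -> retained
  expect_false("fourfold" %in% res$retained)  # |log2(40.5/10.5)| ~ 1.95
  expect_true("mild" %in% res$retained)       # |log2(15.5/10.5)| ~ 0.56

  # absolute mode is symmetric in replicate order
  swapped <- replicate_filter(m[, c(2, 1)], threshold = 1)
  expect_setequal(res$retained, swapped$retained)

  # signed mode keeps features where replicate 2 vastly exceeds replicate 1
  up_in_r2 <- matrix(c(10L, 100L), 1, 2, dimnames = list("f", c("r1", "r2")))
  expect_length(replicate_filter(up_in_r2, signed = TRUE)$retained, 1L)
  expect_length(replicate_filter(up_in_r2, signed = FALSE)$retained, 0L)

  expect_error(replicate_filter(matrix(1:9, 3, 3)), "two replicate")
})

test_that("condition correlation reproduces exact and null cases", {
  set.seed(17)
  vals <- matrix(exp(rnorm(40)), 20, 2,
                 dimnames = list(sprintf("g%02d", 1:20), c("r1", "r2")))
  self <- correlate_conditions(vals, vals)
  expect_equal(self$r, 1.0, tolerance = 1e-12)
  expect_equal(self$n, 20L)

  inv <- 1 / vals  # log2 of the mean is not exactly -x, so build exact pairs
  x <- exp(seq(-3, 3, length.out = 20))
  a <- matrix(x, 20, 1, dimnames = list(sprintf("g%02d", 1:20), "r1"))
  b <- matrix(1 / x, 20, 1, dimnames = list(sprintf("g%02d", 1:20), "r1"))
  anti <- correlate_conditions(a, b, pseudocount = 0)
  expect_equal(anti$r, -1.0, tolerance = 1e-12)

  expect_error(correlate_conditions(vals[1:2, , drop = FALSE], vals),
               "at least 3")

  # independent features: |r| should be small for almost all seeds
  small <- 0L
  for (s in 1:20) {
    set.seed(s)
    aa <- matrix(exp(rnorm(1000)), 1000, 1,
                 dimnames = list(sprintf("g%04d", 1:1000), "r"))
    bb <- matrix(exp(rnorm(1000)), 1000, 1,
                 dimnames = list(sprintf("g%04d", 1:1000), "r"))
    if (abs(correlate_conditions(aa, bb)$r) < 0.1) small <- small + 1L
  }
  expect_gte(small, 19L)
})

test_that("subset mode restricts the correlation to a named panel", {
  set.seed(19)
  m1 <- matrix(exp(rnorm(30)), 15, 2,
               dimnames = list(sprintf("g%02d", 1:15), c("r1", "r2")))
  m2 <- m1 * matrix(exp(rnorm(30, 0, 0.1)), 15, 2)
  panel <- sprintf("g%02d", 1:5)
  sub <- correlate_conditions(m1, m2, subset = panel)
  expect_equal(sub$n, 5L)
  expect_setequal(sub$table$feature_id, panel)
})

test_that("tRNA grouping sums counts before RPM and cancels on one group", {
  ann <- data.frame(feature_id = c("R-TCT-1-1", "R-TCT-2-1"),
                    amino_acid = "R", anticodon = "TCT",
                    isodecoder_id = c("R-TCT-1", "R-TCT-2"))
  m <- matrix(c(100L, 200L, 150L, 250L, 300L, 600L, 450L, 750L), 2, 4,
              dimnames = list(ann$feature_id,
                              c("untreated_1", "untreated_2",
                                "treated_1", "treated_2")))
  # single anticodon group holds everything: RPM is 1e6 on both sides
  fc <- trna_group_fold_change(count_matrix(m), ann,
                               treated = c("treated_1", "treated_2"),
                               untreated = c("untreated_1", "untreated_2"),
                               level = "ANTICODON")
  expect_equal(nrow(fc), 1L)
  expect_equal(fc$log2fc, 0, tolerance = 1e-12)

  expect_error(trna_group_fold_change(count_matrix(m), ann[1, ],
                                      "treated_1", "untreated_1", "TRNA"),
               "annotation missing")
})

test_that("planted suppressor fold is recovered at the isodecoder level", {
  sim <- sim_trna_matrix(planted_fold = 1.5, seed = 23)
  iso <- trna_group_fold_change(sim$cm, sim$annotation, sim$treated,
                                sim$untreated, level = "ISODECODER")
  expect_lt(abs(iso$log2fc[iso$feature_id == "R-TCT-1"] - log2(1.5)), 0.15)
  arg <- arg_isoacceptor_report(iso, sim$annotation)
  expect_true("R-TCT-1" %in% arg$feature_id)
  expect_false(any(!grepl("^R-", arg$feature_id)))
  other_arg <- arg$log2fc[arg$feature_id != "R-TCT-1"]
  expect_lt(max(abs(other_arg)), 0.15)
})

test_that("planted log2 folds are recovered across the stated grid", {
  folds <- c(-1, 0, 0.585, 1)
  ids <- sprintf("f%04d", 1:4)
  for (s in 1:5) {
    sim <- sim_count_matrix(40, n_replicates = 2, nb_dispersion = 5e-4,
                            planted_fold = setNames(2^folds, ids),
                            base_mean = 5000, seed = 400 + s)
    fc <- trna_group_fold_change(
      sim$cm,
      data.frame(feature_id = rownames(sim$cm$counts),
                 amino_acid = "X", anticodon = "XXX",
                 isodecoder_id = rownames(sim$cm$counts)),
      sim$treated, sim$untreated, level = "TRNA")
    got <- fc$log2fc[match(ids, fc$feature_id)]
    expect_true(all(abs(got - folds) < 0.15))
  }
})
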