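test_that("deletion_rate is the binomial ML estimate with a depth floor", {
  expect_equal(deletion_rate(100, 25), 0.25)
  expect_equal(deletion_rate(50, 0), 0)
  expect_true(is.na(deletion_rate(19, 5, min_depth = 20)))
  expect_equal(deletion_rate(c(100, 10), c(25, 1), min_depth = 20),
               c(0.25, NA))
  expect_error(deletion_rate(10, 11), "exceed")
})

test_that("contingency_test matches exact references and fisher.test", {
  expect_equal(contingency_test(0, 100, 0, 100), 1.0)
  # all-or-nothing 5v5 table: 2 of the C(10,5)=252 equi-probable splits
  expect_equal(contingency_test(5, 5, 0, 5), 2 / 252, tolerance = 1e-12)
  # reference oracle for the worked table
  expect_lt(abs(contingency_test(30, 100, 2, 100) -
                  stats::fisher.test(matrix(c(30, 70, 2, 98), 2,
                                            byrow = TRUE))$p.value), 1e-10)
  expect_error(contingency_test(0, 0, 1, 10), "depth > 0")
  expect_error(contingency_test(11, 10, 0, 10), "exceed")
})

test_that("contingency_test agrees with fisher.test on random tables", {
  set.seed(42)
  for (i in 1:200) {
    n1 <- sample(1:80, 1); n2 <- sample(1:80, 1)
    x1 <- sample(0:n1, 1); x2 <- sample(0:n2, 1)
    p_ref <- stats::fisher.test(matrix(c(x1, n1 - x1, x2, n2 - x2), 2,
                                       byrow = TRUE))$p.value
    expect_lt(abs(contingency_test(x1, n1, x2, n2) - p_ref), 1e-10)
  }
})

test_that("the four-criterion caller flags exactly the constructed sites", {
  counts <- rbind(
    # planted off-target: 0.40 vs 0.02, PRAISE(-) 0.01
    locus_counts("t1", 100, 1000, 400, 20, 10, 10),
    # null: equal rates
    locus_counts("t1", 200, 1000, 20, 20, 10, 10),
    # between thresholds: +0.08 passes c1 (5%) but fails c4 (10%)
    locus_counts("t1", 300, 1000, 100, 20, 10, 10))
  calls <- call_offtarget_sites(counts)
  calls <- calls[order(calls$pos), ]
  expect_equal(calls$is_offtarget, c(TRUE, FALSE, FALSE))
  expect_equal(calls$c1, c(TRUE, FALSE, TRUE))
  expect_equal(calls$c4, c(TRUE, FALSE, FALSE))
  expect_true(all(calls$c2))
  expect_true(calls$p_value[1] < 0.005)
  # hand check of criterion 1/4 arithmetic on the planted row
  expect_equal(calls$delta_plus_treated[1] - calls$delta_plus_untreated[1],
               0.38)
})

test_that("loci missing a condition are reported incomplete, never dropped", {
  counts <- locus_counts("t1", 100, 1000, 400, 20, 10, 10)
  counts <- counts[counts$chemistry != "PRAISE_MINUS" |
                     counts$treatment != "TREATED", ]
  calls <- call_offtarget_sites(counts)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$status, "incomplete")
  expect_false(calls$is_offtarget)
  # same for a condition present but below the depth floor
  shallow <- rbind(locus_counts("t2", 5, 1000, 300, 20, 10, 10))
  shallow$depth[shallow$chemistry == "PRAISE_MINUS"] <- 10L
  shallow$deletions[shallow$chemistry == "PRAISE_MINUS"] <- 0L
  calls2 <- call_offtarget_sites(shallow)
  expect_equal(calls2$status, "incomplete")
})

test_that("replicates are pooled by summing counts before testing", {
  one <- locus_counts("t1", 9, 500, 200, 10, 5, 5)
  two <- locus_counts("t1", 9, 500, 200, 10, 5, 5)
  two$sample_id <- paste0(two$sample_id, "_rep2")
  pooled <- call_offtarget_sites(rbind(one, two))
  direct <- call_offtarget_sites(locus_counts("t1", 9, 1000, 400, 20, 10, 10))
  expect_equal(pooled$p_value, direct$p_value)
  expect_equal(pooled$delta_plus_treated, direct$delta_plus_treated)
})

test_that("raising the increase threshold can only shrink the call set", {
  set.seed(7)
  sites <- data.frame(transcript_id = sprintf("t%03d", 1:300), pos = 50,
                      delta_plus_treated = runif(300, 0, 0.4),
                      delta_plus_untreated = 0.02)
  sc <- sim_praise_counts(sites, background_minus = 0.01, depth = 500,
                          seed = 7)
  prev <- NULL
  for (thr in c(0.05, 0.10, 0.20, 0.30)) {
    calls <- call_offtarget_sites(sc, pipeline_config(delta_increase_min = thr))
    called <- calls$transcript_id[calls$is_offtarget]
    if (!is.null(prev)) expect_true(all(called %in% prev))
    prev <- called
  }
})

test_that("under the null, criterion 3 alone fires at most 1% of loci", {
  for (s in 1:3) {
    sites <- data.frame(transcript_id = sprintf("t%04d", 1:1000), pos = 10,
                        delta_plus_treated = 0.02,
                        delta_plus_untreated = 0.02)
    sc <- sim_praise_counts(sites, background_minus = 0.02, depth = 500,
                            seed = s)
    calls <- call_offtarget_sites(sc)
    expect_lte(mean(calls$c3), 0.01)
  }
})

test_that("endogenous site calls follow their three rules", {
  calls <- call_endogenous_sites(rbind(
    locus_counts("t1", 1, 1000, 0, 300, 0, 10),   # endogenous 0.30
    locus_counts("t1", 2, 1000, 0, 10, 0, 10),    # too low (0.01)
    locus_counts("t1", 3, 1000, 0, 300, 0, 100))) # PRAISE(-) at 0.10
  calls <- calls[order(calls$pos), ]
  expect_equal(calls$is_endogenous, c(TRUE, FALSE, FALSE))
})

test_that("stoichiometry comparison counts shifted sites", {
  a <- data.frame(transcript_id = "t1", pos = 1:5,
                  delta = c(0.2, 0.3, 0.4, 0.5, 0.6))
  same <- compare_stoichiometry(a, a, threshold = 0.1)
  expect_true(all(same$table$diff == 0))
  expect_equal(same$n_shifted, 0L)

  b <- a
  b$delta[3] <- b$delta[3] + 0.2
  shift <- compare_stoichiometry(b, a, threshold = 0.1)
  expect_equal(shift$n_shifted, 1L)
  expect_equal(shift$table$pos[abs(shift$table$diff) > 0.1], 3L)

  c_ <- data.frame(transcript_id = "t9", pos = 1:3, delta = 0.5)
  expect_warning(empty <- compare_stoichiometry(a, c_), "no shared loci")
  expect_equal(empty$n_shared, 0L)
})

test_that("predicted loci are checked against calls with depth awareness", {
  counts <- rbind(locus_counts("t1", 100, 1000, 400, 20, 10, 10),
                  locus_counts("t1", 200, 1000, 20, 20, 10, 10))
  calls <- call_offtarget_sites(counts)
  pred <- data.frame(transcript_id = c("t1", "t1", "t1"),
                     target_pos = c(100L, 200L, 999L))
  rep <- check_predicted_loci(calls, pred)
  expect_equal(rep$n_called, 1L)
  expect_equal(rep$table$status, c("called", "not_called", "no_data"))

  shallow <- locus_counts("t2", 5, 10, 3, 0, 0, 0)
  calls2 <- call_offtarget_sites(shallow)
  rep2 <- check_predicted_loci(calls2, data.frame(transcript_id = "t2",
                                                  target_pos = 5L))
  expect_equal(rep2$table$status, "insufficient_depth")
  expect_equal(rep2$n_called, 0L)
})
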