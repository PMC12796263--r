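#' Deletion-rate estimate for a site
#'
#' Pseudouridine stoichiometry is read out as the per-site deletion rate
#' deletions / depth, the maximum-likelihood binomial estimate. Sites covered
#' by fewer than `min_depth` reads get `NA` (undefined, excluded downstream)
#' rather than a noisy value.
#'
#' @param depth,deletions integer vectors (recycled together).
#' @param min_depth minimum covering reads for a defined rate.
#' @return numeric vector of rates in \[0, 1\], `NA` where depth is below
#'   `min_depth`.
#' @export
deletion_rate <- function(depth, deletions, min_depth = 20L) {
  if (any(deletions > depth, na.rm = TRUE))
    stop("deletions exceed depth")
  rate <- deletions / depth
  rate[depth < min_depth] <- NA_real_
  rate
}

#' Two-sided Fisher exact test on a 2x2 deletion table
#'
#' Tests whether the deletion proportion differs between a PRAISE(+) and a
#' PRAISE(-) sample at one site. The two-sided p-value sums the
#' hypergeometric probabilities of all tables (given the margins) no more
#' likely than the observed one, with the standard relative tie tolerance
#' 1 + 1e-7. A chi-squared approximation is available for very deep sites
#' via `method = "chisq"`.
#'
#' @param del_plus,depth_plus deletions and depth in the PRAISE(+) sample.
#' @param del_minus,depth_minus deletions and depth in the PRAISE(-) sample.
#' @param method `"fisher"` (exact) or `"chisq"`.
#' @return p-value in \[0, 1\].
#' @export
contingency_test <- function(del_plus, depth_plus, del_minus, depth_minus,
                             method = c("fisher", "chisq")) {
  method <- match.arg(method)
  if (depth_plus <= 0 || depth_minus <= 0)
    stop("both samples need depth > 0 for the contingency test")
  if (del_plus > depth_plus || del_minus > depth_minus)
    stop("deletions exceed depth")
  if (method == "chisq") {
    tab <- matrix(c(del_plus, depth_plus - del_plus,
                    del_minus, depth_minus - del_minus), nrow = 2)
    return(suppressWarnings(stats::chisq.test(tab)$p.value))
  }
  fisher_p(del_plus, depth_plus, del_minus, depth_minus)
}

# Two-sided Fisher p for one 2x2 table with fixed margins.
# k ~ Hypergeometric(m = total deletions, n = total non-deletions,
#                    draws = depth_plus); observed k = del_plus.
fisher_p <- function(del_plus, depth_plus, del_minus, depth_minus) {
  m <- del_plus + del_minus
  n <- (depth_plus - del_plus) + (depth_minus - del_minus)
  lo <- max(0L, depth_plus - n)
  hi <- min(depth_plus, m)
  k <- lo:hi
  d <- stats::dhyper(k, m, n, depth_plus)
  obs <- d[k == del_plus]
  min(1, sum(d[d <= obs * (1 + 1e-7)]))
}

# Vectorised Fisher p over site tables (plain loop; each table is cheap).
fisher_p_vec <- function(del_plus, depth_plus, del_minus, depth_minus) {
  mapply(fisher_p, del_plus, depth_plus, del_minus, depth_minus)
}

# Pool replicate counts per (locus, chemistry, treatment) and spread the four
# conditions into columns. Returns one row per locus.
pool_conditions <- function(site_table) {
  key <- paste(site_table$transcript_id, site_table$pos,
               site_table$chemistry, site_table$treatment, sep = "\r")
  depth <- tapply(site_table$depth, key, sum)
  dels <- tapply(site_table$deletions, key, sum)
  parts <- do.call(rbind, strsplit(names(depth), "\r", fixed = TRUE))
  pooled <- data.frame(
    transcript_id = parts[, 1], pos = as.integer(parts[, 2]),
    chemistry = parts[, 3], treatment = parts[, 4],
    depth = as.integer(depth), deletions = as.integer(dels),
    stringsAsFactors = FALSE)
  locus <- paste(pooled$transcript_id, pooled$pos, sep = "\r")
  loci <- unique(locus)
  cols <- c(PT = "PRAISE_PLUS.TREATED", PU = "PRAISE_PLUS.UNTREATED",
            MT = "PRAISE_MINUS.TREATED", MU = "PRAISE_MINUS.UNTREATED")
  cond <- paste(pooled$chemistry, pooled$treatment, sep = ".")
  out <- data.frame(transcript_id = sub("\r.*", "", loci),
                    pos = as.integer(sub(".*\r", "", loci)),
                    stringsAsFactors = FALSE)
  for (nm in names(cols)) {
    idx <- match(paste(loci, cols[nm], sep = "\r"), paste(locus, cond, sep = "\r"))
    out[[paste0("depth_", nm)]] <- pooled$depth[idx]
    out[[paste0("del_", nm)]] <- pooled$deletions[idx]
  }
  out[order(out$transcript_id, out$pos), , drop = FALSE]
}

#' Call off-target pseudouridine sites with the four-criterion filter
#'
#' A site is called an off-target modification when all four criteria hold:
#' \enumerate{
#'   \item the absolute deletion-rate difference between treated and
#'     untreated PRAISE(+) samples exceeds `delta_diff_min` (5%);
#'   \item every PRAISE(-) deletion rate is below `praise_minus_max` (5%),
#'     i.e. the signal is chemistry-dependent;
#'   \item the contingency test between the treated PRAISE(+) and treated
#'     PRAISE(-) samples gives p below `p_max` (0.005);
#'   \item the treated PRAISE(+) rate exceeds the untreated one by more than
#'     `delta_increase_min` (10%).
#' }
#' Replicates are pooled by summing counts per condition before rates and
#' tests are computed. Loci missing a condition, or with any required rate
#' undefined at `min_depth`, are reported with status `"incomplete"`, never
#' silently dropped.
#'
#' @param site_table site-count data.frame (layout of [read_site_counts()])
#'   covering the four chemistry x treatment conditions.
#' @param config a [pipeline_config()].
#' @return data.frame sorted by (transcript, pos) with the four per-condition
#'   rates, `p_value`, criterion flags `c1..c4`, `is_offtarget`, `delta`
#'   (treated PRAISE(+) rate) and `status`.
#' @export
call_offtarget_sites <- function(site_table, config = pipeline_config()) {
  w <- pool_conditions(site_table)
  md <- config$min_depth
  w$delta_plus_treated <- deletion_rate(w$depth_PT, w$del_PT, md)
  w$delta_plus_untreated <- deletion_rate(w$depth_PU, w$del_PU, md)
  w$delta_minus_treated <- deletion_rate(w$depth_MT, w$del_MT, md)
  w$delta_minus_untreated <- deletion_rate(w$depth_MU, w$del_MU, md)

  complete <- !is.na(w$delta_plus_treated) & !is.na(w$delta_plus_untreated) &
    !is.na(w$delta_minus_treated) & !is.na(w$delta_minus_untreated)

  diff <- w$delta_plus_treated - w$delta_plus_untreated
  w$c1 <- abs(diff) > config$delta_diff_min
  w$c2 <- w$delta_minus_treated < config$praise_minus_max &
    w$delta_minus_untreated < config$praise_minus_max
  w$p_value <- NA_real_
  idx <- which(complete)
  if (length(idx))
    w$p_value[idx] <- fisher_p_vec(w$del_PT[idx], w$depth_PT[idx],
                                   w$del_MT[idx], w$depth_MT[idx])
  if (config$contingency_method == "chisq" && length(idx))
    w$p_value[idx] <- mapply(function(a, b, c, d)
      contingency_test(a, b, c, d, method = "chisq"),
      w$del_PT[idx], w$depth_PT[idx], w$del_MT[idx], w$depth_MT[idx])
  w$c3 <- w$p_value < config$p_max
  w$c4 <- diff > config$delta_increase_min
  w$is_offtarget <- complete & w$c1 & w$c2 & w$c3 & w$c4
  w$is_offtarget[!complete] <- FALSE
  w$status <- ifelse(complete, "ok", "incomplete")
  w$delta <- w$delta_plus_treated
  rownames(w) <- NULL
  w
}

#' Call endogenous pseudouridine sites from untreated samples
#'
#' An endogenous site has an untreated PRAISE(+) deletion rate of at least
#' `endogenous_min`, PRAISE(-) rates below `praise_minus_max`, and an
#' untreated PRAISE(+) vs PRAISE(-) contingency p below `p_max`. These
#' thresholds are config-exposed defaults, not asserted constants.
#'
#' @inheritParams call_offtarget_sites
#' @return data.frame with rates, `p_value`, `is_endogenous`, `delta`
#'   (untreated PRAISE(+) rate) and `status`.
#' @export
call_endogenous_sites <- function(site_table, config = pipeline_config()) {
  w <- pool_conditions(site_table)
  md <- config$min_depth
  w$delta_plus_untreated <- deletion_rate(w$depth_PU, w$del_PU, md)
  w$delta_minus_untreated <- deletion_rate(w$depth_MU, w$del_MU, md)
  complete <- !is.na(w$delta_plus_untreated) & !is.na(w$delta_minus_untreated)
  w$p_value <- NA_real_
  idx <- which(complete)
  if (length(idx))
    w$p_value[idx] <- fisher_p_vec(w$del_PU[idx], w$depth_PU[idx],
                                   w$del_MU[idx], w$depth_MU[idx])
  w$is_endogenous <- complete &
    w$delta_plus_untreated >= config$endogenous_min &
    w$delta_minus_untreated < config$praise_minus_max &
    w$p_value < config$p_max
  w$is_endogenous[!complete] <- FALSE
  w$status <- ifelse(complete, "ok", "incomplete")
  w$delta <- w$delta_plus_untreated
  rownames(w) <- NULL
  w
}

#' Compare site stoichiometry between two call sets
#'
#' Joins two call tables on (transcript, pos) and reports the per-site
#' deletion-rate difference (`delta` column of each table, a minus b), plus
#' the count of shared sites whose absolute difference exceeds the shift
#' threshold. A consistent-stoichiometry result is `n_shifted = 0`.
#'
#' @param calls_a,calls_b call tables carrying `transcript_id`, `pos`,
#'   `delta`.
#' @param threshold absolute difference counted as a shift.
#' @return `list(table, n_shared, n_shifted)`; empty overlap gives an empty
#'   table with a warning.
#' @export
compare_stoichiometry <- function(calls_a, calls_b, threshold = 0.1) {
  key_a <- paste(calls_a$transcript_id, calls_a$pos)
  key_b <- paste(calls_b$transcript_id, calls_b$pos)
  shared <- intersect(key_a, key_b)
  if (!length(shared)) {
    warning("no shared loci between the two call sets")
    return(list(table = data.frame(transcript_id = character(0),
                                   pos = integer(0), delta_a = numeric(0),
                                   delta_b = numeric(0), diff = numeric(0)),
                n_shared = 0L, n_shifted = 0L))
  }
  ia <- match(shared, key_a)
  ib <- match(shared, key_b)
  tab <- data.frame(transcript_id = calls_a$transcript_id[ia],
                    pos = calls_a$pos[ia],
                    delta_a = calls_a$delta[ia],
                    delta_b = calls_b$delta[ib])
  tab$diff <- tab$delta_a - tab$delta_b
  tab <- tab[order(tab$transcript_id, tab$pos), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, n_shared = nrow(tab),
       n_shifted = sum(abs(tab$diff) > threshold, na.rm = TRUE))
}

#' Check predicted guide-complementary loci against observed calls
#'
#' For each predicted off-target locus (the editable-T position of a guide
#' match), reports the four condition rates and whether the site was called;
#' loci without adequate coverage are labelled rather than dropped. The
#' no-off-target conclusion corresponds to `n_called = 0`.
#'
#' @param calls output of [call_offtarget_sites()].
#' @param predicted data.frame of guide matches with `transcript_id` and
#'   `target_pos` (0-based editable-T offset), e.g. from
#'   [scan_guide_complementarity()].
#' @return `list(table, n_predicted, n_called)`.
#' @export
check_predicted_loci <- function(calls, predicted) {
  key_c <- paste(calls$transcript_id, calls$pos)
  key_p <- paste(predicted$transcript_id, predicted$target_pos)
  idx <- match(key_p, key_c)
  tab <- data.frame(transcript_id = predicted$transcript_id,
                    pos = predicted$target_pos,
                    stringsAsFactors = FALSE)
  tab$delta_plus_treated <- calls$delta_plus_treated[idx]
  tab$delta_plus_untreated <- calls$delta_plus_untreated[idx]
  tab$delta_minus_treated <- calls$delta_minus_treated[idx]
  tab$delta_minus_untreated <- calls$delta_minus_untreated[idx]
  tab$is_offtarget <- calls$is_offtarget[idx]
  tab$status <- ifelse(is.na(idx), "no_data",
                ifelse(calls$status[idx] == "incomplete",
                       "insufficient_depth",
                ifelse(calls$is_offtarget[idx], "called", "not_called")))
  tab$is_offtarget[is.na(tab$is_offtarget)] <- FALSE
  list(table = tab, n_predicted = nrow(tab),
       n_called = sum(tab$status == "called"))
}

#' Write a site-call table with 1-based positions
#'
#' Rates are written to 4 decimals and p-values in scientific notation.
#'
#' @param calls call table from [call_offtarget_sites()] or
#'   [call_endogenous_sites()].
#' @param path output TSV path.
#' @export
write_call_table <- function(calls, path) {
  out <- calls
  out$pos_1based <- out$pos + 1L
  out$pos <- NULL
  rate_cols <- grep("^delta", names(out), value = TRUE)
  for (rc in rate_cols) out[[rc]] <- sprintf("%.4f", out[[rc]])
  if ("p_value" %in% names(out))
    out$p_value <- sprintf("%.4e", out$p_value)
  front <- c("transcript_id", "pos_1based")
  out <- out[c(front, setdiff(names(out), front))]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
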