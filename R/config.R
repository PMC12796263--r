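#' Pipeline configuration
#'
#' Central ledger of every tunable threshold used across the pipeline, with
#' the defaults used throughout the analyses. All site-calling, filtering and
#' inclusion rules read their cutoffs from this object so that a single config
#' (optionally loaded from YAML, see [read_pipeline_config()]) governs a run.
#'
#' @param delta_diff_min minimum absolute deletion-rate difference between
#'   treated and untreated PRAISE(+) samples for an off-target call
#'   (criterion 1; default 0.05).
#' @param praise_minus_max maximum deletion rate tolerated in any PRAISE(-)
#'   sample (criterion 2; default 0.05).
#' @param p_max contingency-test p-value cutoff (criterion 3; default 0.005).
#' @param delta_increase_min minimum signed increase of the treated over the
#'   untreated PRAISE(+) deletion rate (criterion 4; default 0.10).
#' @param endogenous_min minimum untreated PRAISE(+) deletion rate for an
#'   endogenous site call (default 0.05).
#' @param max_mismatches mismatch budget for the guide-complementarity scan
#'   over the 15 scored positions (default 3).
#' @param min_umi_family minimum reads per UMI family; smaller families are
#'   discarded (default 3).
#' @param max_read_mismatches maximum substitutions tolerated between a UMI
#'   consensus and the amplicon reference (default 2); deletions at the target
#'   are not counted as mismatches.
#' @param te_min_rna_cpm minimum RNA-seq CPM in every replicate for inclusion
#'   in the translation-efficiency analysis (default 1).
#' @param te_min_ribo_count minimum Ribo-seq raw read count for inclusion
#'   (default 20).
#' @param te_direction `"rna_over_ribo"` (as the analyses report TE) or
#'   `"ribo_over_rna"` (the conventional orientation).
#' @param rep_filter_log2 absolute log2(rep1/rep2) above which a feature is
#'   judged irreproducible and removed (default 1).
#' @param min_depth minimum covering reads for a deletion rate to be defined
#'   (default 20).
#' @param p_site_offset fixed 5' offset (nt) used to place the ribosomal
#'   P-site inside a footprint (default 12).
#' @param footprint_lengths inclusive footprint-length window retained for
#'   P-site assignment (default 26:34).
#' @param rrts_event_threshold RRTS above which a transcript is flagged as a
#'   readthrough event (default 0.01).
#' @param rrts_min_cds_reads minimum CDS P-site reads for RRTS to be defined
#'   (default 20).
#' @param top_k number of top-ranked guide-complementary regions reported
#'   (default 50).
#' @param pseudocount added before any log2 of counts (default 0.5).
#' @param stoich_shift_threshold absolute delta-rate difference above which a
#'   site counts as shifted in stoichiometry comparisons (default 0.1).
#' @param consensus_mode `"column"` (per-position majority, the default) or
#'   `"modal"` (most frequent whole read in the family). Column majority is
#'   the standard UMI consensus and stays accurate for small families at
#'   realistic per-base error; modal selection needs several error-free
#'   copies per family.
#' @param contingency_method `"fisher"` (exact, default) or `"chisq"`.
#' @param rep_filter_signed if `TRUE` the replicate filter uses the signed
#'   log-ratio exactly as printed instead of its absolute value.
#' @param seed integer seed recorded with the run.
#'
#' @return a named list with class `"pipeline_config"`.
#' @export
pipeline_config <- function(delta_diff_min = 0.05,
                            praise_minus_max = 0.05,
                            p_max = 0.005,
                            delta_increase_min = 0.10,
                            endogenous_min = 0.05,
                            max_mismatches = 3L,
                            min_umi_family = 3L,
                            max_read_mismatches = 2L,
                            te_min_rna_cpm = 1,
                            te_min_ribo_count = 20L,
                            te_direction = c("rna_over_ribo", "ribo_over_rna"),
                            rep_filter_log2 = 1.0,
                            min_depth = 20L,
                            p_site_offset = 12L,
                            footprint_lengths = 26:34,
                            rrts_event_threshold = 0.01,
                            rrts_min_cds_reads = 20L,
                            top_k = 50L,
                            pseudocount = 0.5,
                            stoich_shift_threshold = 0.1,
                            consensus_mode = c("column", "modal"),
                            contingency_method = c("fisher", "chisq"),
                            rep_filter_signed = FALSE,
                            seed = 1L) {
  cfg <- list(
    delta_diff_min = delta_diff_min,
    praise_minus_max = praise_minus_max,
    p_max = p_max,
    delta_increase_min = delta_increase_min,
    endogenous_min = endogenous_min,
    max_mismatches = as.integer(max_mismatches),
    min_umi_family = as.integer(min_umi_family),
    max_read_mismatches = as.integer(max_read_mismatches),
    te_min_rna_cpm = te_min_rna_cpm,
    te_min_ribo_count = as.integer(te_min_ribo_count),
    te_direction = match.arg(te_direction),
    rep_filter_log2 = rep_filter_log2,
    min_depth = as.integer(min_depth),
    p_site_offset = as.integer(p_site_offset),
    footprint_lengths = as.integer(footprint_lengths),
    rrts_event_threshold = rrts_event_threshold,
    rrts_min_cds_reads = as.integer(rrts_min_cds_reads),
    top_k = as.integer(top_k),
    pseudocount = pseudocount,
    stoich_shift_threshold = stoich_shift_threshold,
    consensus_mode = match.arg(consensus_mode),
    contingency_method = match.arg(contingency_method),
    rep_filter_signed = isTRUE(rep_filter_signed),
    seed = as.integer(seed)
  )
  probs <- c("delta_diff_min", "praise_minus_max", "p_max",
             "delta_increase_min", "endogenous_min", "rrts_event_threshold")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("config field '", p, "' must be a probability in [0, 1]")
  }
  ints <- c("max_mismatches", "min_umi_family", "max_read_mismatches",
            "te_min_ribo_count", "min_depth", "top_k", "rrts_min_cds_reads")
  for (p in ints) {
    v <- cfg[[p]]
    if (length(v) != 1L || is.na(v) || v < 0L)
      stop("config field '", p, "' must be a non-negative integer")
  }
  if (cfg$pseudocount <= 0)
    stop("config field 'pseudocount' must be > 0")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; omitted keys keep their defaults.
#'
#' @param path path to a YAML file whose keys match [pipeline_config()]
#'   arguments.
#' @return a `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-22s %s\n", nm,
                if (length(v) > 6) paste0(v[1], "..", v[length(v)])
                else paste(v, collapse = " ")))
  }
  invisible(x)
}
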