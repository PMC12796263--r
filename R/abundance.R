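# Expression-stability analyses: library-size normalization, replicate
# reproducibility filtering, between-condition correlation, and tRNA
# anticodon/isodecoder fold changes.

#' Normalize a count matrix
#'
#' CPM and RPM are counts x 1e6 / library size (column sum); RPKM further
#' divides by the feature length in kb. CPM/RPM columns sum to 1e6 exactly
#' (up to floating point).
#'
#' @param cm a RAW [count_matrix()].
#' @param mode `"CPM"`, `"RPM"` or `"RPKM"` (RPKM needs feature lengths).
#' @return a normalized `count_matrix`.
#' @export
normalize_counts <- function(cm, mode = c("CPM", "RPM", "RPKM")) {
  mode <- match.arg(mode)
  if (cm$normalization != "RAW")
    stop("input is already normalized (", cm$normalization, ")")
  libsize <- colSums(cm$counts)
  if (any(libsize == 0)) stop("zero library size in column ",
                              which(libsize == 0)[1])
  per_million <- t(t(cm$counts) * 1e6 / libsize)
  if (mode == "RPKM") {
    if (is.null(cm$feature_lengths))
      stop("RPKM requires feature lengths")
    per_million <- per_million / (cm$feature_lengths / 1e3)
  }
  structure(list(counts = per_million, feature_lengths = cm$feature_lengths,
                 normalization = mode), class = "count_matrix")
}

#' Filter features by replicate reproducibility
#'
#' Removes features whose between-replicate log2 ratio
#' log2((rep1 + eps) / (rep2 + eps)) exceeds the threshold in absolute
#' value (or, with `signed = TRUE`, as the signed ratio exactly as the rule
#' is printed). Applied to raw counts.
#'
#' @param cm a `count_matrix` with exactly two replicate columns (or a
#'   two-column matrix).
#' @param threshold log2 cutoff (default 1).
#' @param pseudocount added to both replicates before the ratio.
#' @param signed use the signed ratio instead of the absolute value.
#' @return `list(retained` (feature ids), `removed` (data.frame with
#'   `feature_id`, `log2_ratio`), `log2_ratio` (named, all features)`)`.
#' @export
replicate_filter <- function(cm, threshold = 1, pseudocount = 0.5,
                             signed = FALSE) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  if (ncol(counts) != 2L)
    stop("replicate_filter expects exactly two replicate columns")
  lr <- log2((counts[, 1] + pseudocount) / (counts[, 2] + pseudocount))
  bad <- if (signed) lr > threshold else abs(lr) > threshold
  list(retained = rownames(counts)[!bad],
       removed = data.frame(feature_id = rownames(counts)[bad],
                            log2_ratio = lr[bad], row.names = NULL,
                            stringsAsFactors = FALSE),
       log2_ratio = lr)
}

#' Correlate expression between two conditions
#'
#' Two-sided Pearson correlation on log2-transformed mean abundances
#' (mean over replicates within each condition, plus pseudocount).
#' Optionally restricted to a named feature panel (e.g. inflammatory
#' factors).
#'
#' @param cm_a,cm_b `count_matrix` objects (normalized or raw) for the two
#'   conditions.
#' @param subset optional character vector of feature ids to restrict to.
#' @param pseudocount added before log2.
#' @return `list(r, p_value, n, table)` where `table` holds the paired
#'   log2 means.
#' @export
correlate_conditions <- function(cm_a, cm_b, subset = NULL,
                                 pseudocount = 0.5) {
  a <- if (inherits(cm_a, "count_matrix")) cm_a$counts else as.matrix(cm_a)
  b <- if (inherits(cm_b, "count_matrix")) cm_b$counts else as.matrix(cm_b)
  shared <- intersect(rownames(a), rownames(b))
  if (!is.null(subset)) shared <- intersect(shared, subset)
  if (length(shared) < 3L)
    stop("need at least 3 shared features for a correlation, got ",
         length(shared))
  x <- log2(rowMeans(a[shared, , drop = FALSE]) + pseudocount)
  y <- log2(rowMeans(b[shared, , drop = FALSE]) + pseudocount)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(shared),
       table = data.frame(feature_id = shared, log2_mean_a = x,
                          log2_mean_b = y, row.names = NULL,
                          stringsAsFactors = FALSE))
}

#' tRNA fold changes at transcript, anticodon or isodecoder level
#'
#' Counts are summed within each group, normalized to RPM per sample, and
#' the treated/untreated log2 fold change of group means is reported.
#' Grouping levels: `"TRNA"` (per transcript), `"ANTICODON"`
#' (amino acid + anticodon family) or `"ISODECODER"` (isodecoder id).
#'
#' @param cm RAW `count_matrix` of tRNA counts.
#' @param annotation data.frame with `feature_id`, `amino_acid`,
#'   `anticodon`, `isodecoder_id`.
#' @param treated,untreated column names of the two sample groups.
#' @param level `"TRNA"`, `"ANTICODON"` or `"ISODECODER"`.
#' @param pseudocount added to RPM means before log2.
#' @return data.frame of fold-change records with `feature_id`,
#'   `group_level`, `mean_treated`, `mean_untreated`, `log2fc`.
#' @export
trna_group_fold_change <- function(cm, annotation, treated, untreated,
                                   level = c("ANTICODON", "TRNA",
                                             "ISODECODER"),
                                   pseudocount = 0.5) {
  level <- match.arg(level)
  counts <- cm$counts
  miss <- setdiff(rownames(counts), annotation$feature_id)
  if (length(miss))
    stop("annotation missing for feature(s): ",
         paste(utils::head(miss, 3), collapse = ", "))
  ann <- annotation[match(rownames(counts), annotation$feature_id), ]
  group <- switch(level,
                  TRNA = ann$feature_id,
                  ANTICODON = paste(ann$amino_acid, ann$anticodon, sep = "-"),
                  ISODECODER = ann$isodecoder_id)
  grouped <- rowsum(counts, group)
  rpm <- t(t(grouped) * 1e6 / colSums(grouped))
  mt <- rowMeans(rpm[, treated, drop = FALSE])
  mu <- rowMeans(rpm[, untreated, drop = FALSE])
  data.frame(feature_id = rownames(grouped),
             group_level = level,
             mean_treated = mt, mean_untreated = mu,
             log2fc = log2((mt + pseudocount) / (mu + pseudocount)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Arginine isoacceptor report
#'
#' Restricts an isodecoder- or transcript-level fold-change table to the
#' arginine isoacceptor family, the panel where only the introduced
#' suppressor tRNA is expected to move.
#'
#' @param fold_changes output of [trna_group_fold_change()].
#' @param annotation tRNA annotation data.frame.
#' @param amino_acid one-letter amino-acid code (default `"R"`).
#' @return the subset of rows whose group contains features of that amino
#'   acid.
#' @export
arg_isoacceptor_report <- function(fold_changes, annotation,
                                   amino_acid = "R") {
  keys <- unique(c(
    annotation$feature_id[annotation$amino_acid == amino_acid],
    annotation$isodecoder_id[annotation$amino_acid == amino_acid],
    paste(annotation$amino_acid, annotation$anticodon,
          sep = "-")[annotation$amino_acid == amino_acid]))
  out <- fold_changes[fold_changes$feature_id %in% keys, , drop = FALSE]
  rownames(out) <- NULL
  out
}
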