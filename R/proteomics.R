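# Amino-acid incorporation at the premature termination codon, from a
# peptide-level abundance table (search-engine output over a composite
# database carrying all 20 residues at the PTC position).

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Amino-acid incorporation rate at the PTC position
#'
#' Peptides supported by a single PSM are discarded (PSM > 1 rule); within
#' each replicate the incorporation fraction of residue X is the summed
#' precursor abundance of retained peptides carrying X at the PTC position
#' divided by the total retained abundance. Replicates are summarized as
#' the mean of per-replicate fractions (default) or by pooling abundances
#' first.
#'
#' @param peptides data.frame with `peptide_id`, `ptc_residue`,
#'   `psm_count`, and one or more `abundance_*` columns (one per
#'   replicate).
#' @param mode `"mean_of_replicates"` or `"pooled"`.
#' @return `list(fractions` (named 20-vector summing to 1),
#'   `per_replicate` (matrix residues x replicates), `dominant` (residue
#'   with the highest mean fraction), `n_retained`)`.
#' @export
incorporation_rate <- function(peptides,
                               mode = c("mean_of_replicates", "pooled")) {
  mode <- match.arg(mode)
  ab_cols <- grep("^abundance", names(peptides), value = TRUE)
  if (!length(ab_cols)) stop("no abundance columns found")
  bad <- setdiff(unique(peptides$ptc_residue), AA_ALPHABET)
  if (length(bad))
    stop("unknown PTC residue code(s): ", paste(bad, collapse = ", "))
  if (any(unlist(peptides[ab_cols]) < 0))
    stop("abundances must be non-negative")
  kept <- peptides[peptides$psm_count > 1L, , drop = FALSE]
  if (!nrow(kept))
    stop("no peptides survive the PSM > 1 filter")

  per_rep <- sapply(ab_cols, function(col) {
    tot <- sum(kept[[col]])
    if (tot <= 0) return(setNames(rep(NA_real_, 20L), AA_ALPHABET))
    s <- tapply(kept[[col]], factor(kept$ptc_residue, levels = AA_ALPHABET),
                sum, default = 0)
    s / tot
  })
  per_rep <- matrix(per_rep, nrow = 20L,
                    dimnames = list(AA_ALPHABET, ab_cols))

  fractions <- if (mode == "mean_of_replicates") {
    rowMeans(per_rep, na.rm = TRUE)
  } else {
    pooled <- rowSums(sapply(ab_cols, function(col)
      tapply(kept[[col]], factor(kept$ptc_residue, levels = AA_ALPHABET),
             sum, default = 0)))
    pooled / sum(pooled)
  }
  list(fractions = fractions, per_replicate = per_rep,
       dominant = names(which.max(fractions)), n_retained = nrow(kept))
}

#' Read a peptide table from TSV
#'
#' Columns: `peptide_id`, `ptc_residue`, `psm_count`, and `abundance_*`
#' replicate columns.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_peptide_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("peptide_id", "ptc_residue", "psm_count")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("peptide table missing column(s): ", paste(miss, collapse = ", "))
  if (!length(grep("^abundance", names(df))))
    stop("peptide table needs at least one abundance_* column")
  df
}
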