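# Targeted-amplicon editing quantification via UMI-consensus deduplication.
#
# Reads sharing a UMI derive from one original molecule; the family
# consensus removes PCR/sequencing error and the per-molecule deletion rate
# at the target base is the amplicon analogue of the deletion-signature
# stoichiometry.

#' Group amplicon reads by UMI
#'
#' Exact-match grouping (no UMI error correction). Families smaller than
#' `min_family` are flagged `retained = FALSE` and excluded from consensus
#' building downstream.
#'
#' @param reads data.frame with `read_id`, `umi`, `sequence`.
#' @param min_family minimum family size retained (default 3).
#' @return list of families, each `list(umi, reads, size, retained)`,
#'   ordered by UMI.
#' @export
group_by_umi <- function(reads, min_family = 3L) {
  if (is.null(reads$umi) || any(is.na(reads$umi) | !nzchar(reads$umi))) {
    bad <- which(is.na(reads$umi) | !nzchar(reads$umi))[1]
    stop("read ", if (!is.null(reads$read_id)) reads$read_id[bad] else bad,
         " has no UMI")
  }
  if (length(unique(nchar(reads$umi))) > 1L)
    stop("UMIs must have uniform length")
  fams <- split(reads$sequence, reads$umi)
  lapply(names(fams), function(u) {
    sz <- length(fams[[u]])
    list(umi = u, reads = fams[[u]], size = sz,
         retained = sz >= min_family)
  })
}

#' Consensus sequence of a UMI family
#'
#' Default mode `"column"` takes the per-position majority over reads of
#' equal length (reads from one molecule share any molecule-level deletion,
#' so lengths agree within a family); `"modal"` selects the most frequent
#' whole read in the family. Ties break to the lexicographically smallest
#' candidate so the result is deterministic and independent of read order.
#'
#' @param family one element of [group_by_umi()] output (or any list with a
#'   `reads` character vector).
#' @param mode `"column"` or `"modal"`.
#' @return consensus sequence string.
#' @export
consensus <- function(family, mode = c("column", "modal")) {
  mode <- match.arg(mode)
  reads <- family$reads
  if (!length(reads)) stop("cannot build a consensus from an empty family")
  if (mode == "modal") {
    tab <- table(reads)
    best <- names(tab)[tab == max(tab)]
    return(min(best))
  }
  lens <- nchar(reads)
  if (length(unique(lens)) > 1L) {
    # column consensus needs one length; keep the majority length class
    # (ties -> shorter), indels being molecule-level events
    lt <- table(lens)
    keep_len <- as.integer(names(lt)[lt == max(lt)])[1]
    reads <- reads[lens == keep_len]
  }
  m <- matrix(unlist(strsplit(reads, "")), nrow = length(reads),
              byrow = TRUE)
  alphabet <- sort(unique(as.vector(m)))
  counts <- vapply(alphabet, function(b) colSums(m == b),
                   numeric(ncol(m)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  # max.col on ties = "first" + alphabetical columns = lexicographic break
  paste(alphabet[max.col(counts, ties.method = "first")], collapse = "")
}

#' Align consensi to the amplicon reference and filter by substitutions
#'
#' Each consensus is globally aligned to the reference (gap-affine, so a
#' 1-nt target deletion is preferred over scattered mismatches).
#' Substitutions and deletions are scored separately: a consensus is removed
#' when its substitution count exceeds `max_mismatches`, while deletions —
#' the editing signal — are never counted as mismatches. A deletion counts
#' as hitting the target when it falls anywhere in the homopolymer run
#' containing the target base (removal of any base in a run is the same
#' molecule, and aligners place such gaps arbitrarily within the run).
#' Consensi whose length difference from the reference exceeds a 3-nt
#' deletion budget (or that are longer than the reference) are flagged
#' unalignable.
#'
#' @param consensi character vector of consensus sequences.
#' @param reference amplicon reference sequence.
#' @param max_mismatches maximum substitutions tolerated (default 2).
#' @param target_pos 0-based offset of the editable base in the reference.
#' @return data.frame with `consensus`, `n_substitutions`,
#'   `deletion_at_target`, `unalignable`, `retained`.
#' @export
filter_alignment_mismatches <- function(consensi, reference,
                                        max_mismatches = 2L, target_pos) {
  if (!is.character(reference) || length(reference) != 1L ||
      !nzchar(reference))
    stop("reference must be a single non-empty sequence")
  reference <- normalize_seq(reference)
  n <- length(consensi)
  out <- data.frame(consensus = consensi,
                    n_substitutions = NA_integer_,
                    deletion_at_target = FALSE,
                    unalignable = FALSE,
                    retained = FALSE,
                    stringsAsFactors = FALSE)
  if (!n) return(out)
  lend <- nchar(consensi) - nchar(reference)
  out$unalignable <- lend > 0L | lend < -3L
  # homopolymer run of the reference containing the target base
  ref_chars <- strsplit(reference, "")[[1]]
  run_lo <- target_pos + 1L
  while (run_lo > 1L && ref_chars[run_lo - 1L] == ref_chars[target_pos + 1L])
    run_lo <- run_lo - 1L
  run_hi <- target_pos + 1L
  while (run_hi < length(ref_chars) &&
         ref_chars[run_hi + 1L] == ref_chars[target_pos + 1L])
    run_hi <- run_hi + 1L
  idx <- which(!out$unalignable)
  if (length(idx)) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAStringSet(consensi[idx]),
      subject = Biostrings::DNAString(reference),
      type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = TRUE),
      gapOpening = 5, gapExtension = 2)
    out$n_substitutions[idx] <- Biostrings::nmismatch(aln)
    dels <- Biostrings::deletion(aln)
    n_del <- S4Vectors::elementNROWS(dels)
    if (any(n_del > 0)) {
      grp <- rep(seq_along(idx), n_del)
      w_all <- unlist(BiocGenerics::width(dels), use.names = FALSE)
      s_all <- unlist(BiocGenerics::start(dels), use.names = FALSE)
      # deletion() reports gap positions in the consensus frame; earlier
      # deletions shift later ones, so add the cumulative deleted width to
      # recover reference coordinates
      offset <- unlist(lapply(split(w_all, grp), function(w)
        cumsum(c(0L, w[-length(w)]))), use.names = FALSE)
      ref_start <- s_all + offset
      ref_end <- ref_start + w_all - 1L
      hit <- ref_end >= run_lo & ref_start <= run_hi
      out$deletion_at_target[idx[unique(grp[hit])]] <- TRUE
    }
  }
  out$retained <- !out$unalignable &
    out$n_substitutions <= max_mismatches
  out$retained[is.na(out$retained)] <- FALSE
  out
}

#' Target deletion rate over retained consensi
#'
#' Fraction of retained consensi carrying a deletion spanning the target
#' position — the per-molecule editing rate of the amplicon.
#'
#' @param filtered output of [filter_alignment_mismatches()].
#' @return rate in \[0, 1\], or `NA` with a warning when nothing is
#'   retained.
#' @export
target_deletion_rate <- function(filtered) {
  kept <- filtered[filtered$retained, , drop = FALSE]
  if (!nrow(kept)) {
    warning("no retained consensi; target deletion rate undefined")
    return(NA_real_)
  }
  mean(kept$deletion_at_target)
}

#' Run the full amplicon quantification pipeline
#'
#' Groups reads by UMI, discards families below the size threshold, builds
#' per-family consensi, filters on substitution count against the
#' reference, and reports the target deletion rate.
#'
#' @param reads data.frame with `read_id`, `umi`, `sequence`.
#' @param reference amplicon reference sequence.
#' @param target_pos 0-based offset of the editable base.
#' @param config a [pipeline_config()] (uses `min_umi_family`,
#'   `max_read_mismatches`, `consensus_mode`).
#' @return `list(families_total, families_retained, consensi_retained,
#'   deletion_rate, consensi, filtered)`.
#' @export
amplicon_pipeline <- function(reads, reference, target_pos,
                              config = pipeline_config()) {
  fams <- group_by_umi(reads, min_family = config$min_umi_family)
  kept <- Filter(function(f) f$retained, fams)
  cons <- vapply(kept, consensus, "", mode = config$consensus_mode)
  filt <- filter_alignment_mismatches(cons, reference,
                                      max_mismatches = config$max_read_mismatches,
                                      target_pos = target_pos)
  filt$umi <- vapply(kept, `[[`, "", "umi")
  rate <- if (nrow(filt)) target_deletion_rate(filt) else NA_real_
  list(families_total = length(fams),
       families_retained = length(kept),
       consensi_retained = sum(filt$retained),
       deletion_rate = rate,
       consensi = cons,
       filtered = filt)
}
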