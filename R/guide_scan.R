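# Guide-complementarity off-target scan.
#
# The guide snoRNA recognises its target through a 17-nt complementary
# window whose central position pairs the editable U; potential off-target
# loci are transcriptome windows matching that pattern. Pattern convention:
# the editable T sits immediately before the single degenerate N, i.e. for
# AATTTACTNAACAGAGG the T at position 8 (1-based) is the edited base and
# position 9 is unconstrained. The remaining 15 positions are scored for
# mismatches.

parse_guide_pattern <- function(pattern) {
  pattern <- normalize_seq(pattern)
  chars <- strsplit(pattern, "")[[1]]
  if (length(chars) != 17L)
    stop("guide pattern must be 17 nt, got ", length(chars))
  n_pos <- which(chars == "N")
  if (length(n_pos) != 1L)
    stop("guide pattern must contain exactly one N")
  if (n_pos < 2L)
    stop("the degenerate N must follow the editable T")
  t_pos <- n_pos - 1L
  if (chars[t_pos] != "T")
    stop("the base before the N must be the editable T")
  if (any(!chars[-n_pos] %in% BASES))
    stop("guide pattern may only contain A/C/G/T/U and one N")
  list(chars = chars, t_pos = t_pos, n_pos = n_pos,
       scored = setdiff(seq_len(17L), c(t_pos, n_pos)))
}

#' Scan a transcriptome for guide-complementary windows
#'
#' Slides the 17-nt guide-complementarity pattern along the sense strand of
#' every transcript and reports each window where (1) the base aligned to
#' the editable position is T, (2) the base at the degenerate N position is
#' unconstrained, and (3) at most `max_mismatches` of the remaining 15
#' scored positions disagree. All matches are reported (no merging of
#' overlaps), sorted by (transcript, start) — the report-all contract of an
#' exhaustive aligner run.
#'
#' @param transcriptome named character vector of transcript sequences
#'   (e.g. from [read_fasta()]).
#' @param pattern 17-nt pattern with one N after the editable T; default is
#'   the suppressor-guide target pattern.
#' @param config a [pipeline_config()]; `max_mismatches` is used.
#' @return data.frame with `transcript_id`, `start` (0-based window offset),
#'   `target_pos` (0-based offset of the editable T), `mismatches`,
#'   `central_base_ok` (always TRUE for emitted rows), `window_seq`.
#' @export
scan_guide_complementarity <- function(transcriptome,
                                       pattern = "AATTTACTNAACAGAGG",
                                       config = pipeline_config()) {
  pat <- parse_guide_pattern(pattern)
  res <- vector("list", length(transcriptome))
  for (i in seq_along(transcriptome)) {
    seq_i <- normalize_seq(transcriptome[[i]])
    L <- nchar(seq_i)
    if (L < 17L) next
    chars <- strsplit(seq_i, "")[[1]]
    starts <- seq_len(L - 16L)            # 1-based window starts
    central_ok <- chars[starts + pat$t_pos - 1L] == "T"
    mm <- integer(length(starts))
    for (j in pat$scored)
      mm <- mm + (chars[starts + j - 1L] != pat$chars[j])
    keep <- central_ok & mm <= config$max_mismatches
    if (!any(keep)) next
    s <- starts[keep]
    res[[i]] <- data.frame(
      transcript_id = names(transcriptome)[i],
      start = s - 1L,
      target_pos = s - 1L + pat$t_pos - 1L,
      mismatches = mm[keep],
      central_base_ok = TRUE,
      window_seq = substring(seq_i, s, s + 16L),
      stringsAsFactors = FALSE)
  }
  res <- res[!vapply(res, is.null, TRUE)]
  if (!length(res))
    return(data.frame(transcript_id = character(0), start = integer(0),
                      target_pos = integer(0), mismatches = integer(0),
                      central_base_ok = logical(0), window_seq = character(0)))
  out <- do.call(rbind, res)
  out <- out[order(out$transcript_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank guide matches and keep the top regions
#'
#' Matches are sorted ascending by mismatch count, ties broken by
#' (transcript_id, start); the first `k` are returned with a `rank` column.
#'
#' @param matches output of [scan_guide_complementarity()].
#' @param k number of regions to keep (default 50).
#' @return the top `k` rows (all rows when fewer), with `rank`.
#' @export
rank_top_regions <- function(matches, k = 50L) {
  if (k <= 0L) stop("k must be positive")
  ord <- order(matches$mismatches, matches$transcript_id, matches$start)
  out <- matches[ord, , drop = FALSE][seq_len(min(k, nrow(matches))), ,
                                      drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Write guide matches as TSV and BED6
#'
#' The TSV carries the 1-based position of the editable T (`pos_1based`);
#' the BED is 0-based half-open over the 17-nt window with the mismatch
#' count as score.
#'
#' @param matches guide-match table.
#' @param tsv_path,bed_path output paths (either may be `NULL` to skip).
#' @export
write_guide_matches <- function(matches, tsv_path = NULL, bed_path = NULL) {
  if (!is.null(tsv_path)) {
    out <- data.frame(transcript_id = matches$transcript_id,
                      pos_1based = matches$target_pos + 1L,
                      window_seq = matches$window_seq,
                      mismatches = matches$mismatches)
    if ("rank" %in% names(matches)) out$rank <- matches$rank
    utils::write.table(out, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(bed_path)) {
    write_bed(data.frame(transcript_id = matches$transcript_id,
                         start = matches$start,
                         end = matches$start + 17L,
                         name = paste0(matches$transcript_id, ":",
                                       matches$target_pos + 1L),
                         score = matches$mismatches), bed_path)
  }
  invisible(NULL)
}
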