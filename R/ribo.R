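# Ribosome-profiling safety metrics: P-site tracks, ribosome readthrough
# score (RRTS), 3'UTR footprint density, stop-codon metagene profile and
# translation efficiency.

#' Assign P-sites to footprints
#'
#' Places the ribosomal P-site at the footprint 5' end plus a fixed offset
#' (default 12 nt), or a per-length offset table. Footprints outside the
#' configured length window, or whose P-site falls outside the transcript,
#' are dropped and counted.
#'
#' @param footprints data.frame with `transcript_id`, `pos5` (0-based 5'
#'   position) and `length`.
#' @param transcript_lengths named integer vector of transcript lengths.
#' @param config a [pipeline_config()] (uses `p_site_offset`,
#'   `footprint_lengths`).
#' @param offset_table optional named vector mapping footprint length to
#'   offset, overriding the fixed offset for listed lengths.
#' @return named list of integer P-site count tracks (one per transcript in
#'   `transcript_lengths`), with attribute `dropped` = number of discarded
#'   footprints.
#' @export
assign_psites <- function(footprints, transcript_lengths,
                          config = pipeline_config(), offset_table = NULL) {
  off <- rep(config$p_site_offset, nrow(footprints))
  if (!is.null(offset_table)) {
    hit <- match(as.character(footprints$length), names(offset_table))
    off[!is.na(hit)] <- offset_table[hit[!is.na(hit)]]
  }
  keep_len <- footprints$length %in% config$footprint_lengths
  psite <- footprints$pos5 + off
  tlen <- transcript_lengths[footprints$transcript_id]
  inside <- !is.na(tlen) & psite >= 0L & psite < tlen
  keep <- keep_len & inside
  dropped <- sum(!keep)
  tracks <- lapply(names(transcript_lengths), function(tx) {
    idx <- keep & footprints$transcript_id == tx
    tabulate(psite[idx] + 1L, nbins = transcript_lengths[[tx]])
  })
  names(tracks) <- names(transcript_lengths)
  attr(tracks, "dropped") <- dropped
  tracks
}

# 0-based half-open readthrough region: from the first nt after the
# annotated stop to the start of the next in-frame stop codon in the 3'UTR,
# or the transcript end if none.
readthrough_region <- function(model) {
  start <- model$cds_end
  end <- model$length
  if (start >= end) return(c(start, start))   # empty: no 3'UTR
  stops <- c("TAA", "TAG", "TGA")
  p <- start
  while (p + 3L <= model$length) {
    codon <- substr(model$sequence, p + 1L, p + 3L)
    if (codon %in% stops) return(c(start, p))
    p <- p + 3L
  }
  c(start, end)
}

#' Ribosome readthrough score for one transcript
#'
#' RRTS is the ratio of P-site density in the stop-codon readthrough region
#' (first nt after the annotated stop up to the next in-frame stop, or the
#' transcript end) to the density within the CDS. Undefined when the CDS has
#' fewer than `rrts_min_cds_reads` P-sites or the transcript has no 3'UTR.
#'
#' @param track integer P-site track for the transcript.
#' @param model a [transcript_model()].
#' @param config a [pipeline_config()] (uses `rrts_min_cds_reads`,
#'   `rrts_event_threshold`).
#' @return one-row data.frame with `transcript_id`, `cds_density`,
#'   `rt_start`, `rt_end`, `rt_density`, `rrts`, `is_event`, `reason`.
#' @export
rrts <- function(track, model, config = pipeline_config()) {
  stopifnot(length(track) == model$length)
  cds_len <- model$cds_end - model$cds_start
  cds_reads <- sum(track[(model$cds_start + 1L):model$cds_end])
  cds_density <- cds_reads / cds_len
  rt <- readthrough_region(model)
  rt_len <- rt[2] - rt[1]
  rec <- data.frame(transcript_id = model$transcript_id,
                    cds_density = cds_density,
                    rt_start = rt[1], rt_end = rt[2],
                    rt_density = NA_real_, rrts = NA_real_,
                    is_event = FALSE, reason = "ok",
                    stringsAsFactors = FALSE)
  if (rt_len == 0L) {
    rec$reason <- "no_utr3"
    return(rec)
  }
  rec$rt_density <- sum(track[(rt[1] + 1L):rt[2]]) / rt_len
  if (cds_reads < config$rrts_min_cds_reads) {
    rec$reason <- "low_cds_coverage"
    return(rec)
  }
  rec$rrts <- rec$rt_density / cds_density
  rec$is_event <- rec$rrts > config$rrts_event_threshold
  rec
}

#' RRTS table over a set of transcripts
#'
#' @param tracks named list of P-site tracks.
#' @param models list of [transcript_model()] objects.
#' @param config a [pipeline_config()].
#' @return data.frame with one [rrts()] row per transcript.
#' @export
rrts_table <- function(tracks, models, config = pipeline_config()) {
  out <- do.call(rbind, lapply(models, function(m)
    rrts(tracks[[m$transcript_id]], m, config)))
  rownames(out) <- NULL
  out
}

#' Compare 3'UTR footprint density between conditions
#'
#' Per-transcript ribosome-protected-fragment density over the 3'UTR
#' (annotated stop to transcript end) in each condition, with the paired
#' difference; the global summary (median difference, fraction increased)
#' is the no-enrichment readout at normal stop codons. Transcripts without
#' a 3'UTR are excluded and counted.
#'
#' @param tracks_treated,tracks_untreated named lists of P-site tracks.
#' @param models list of [transcript_model()] objects.
#' @return `list(table, median_diff, fraction_increased, n_excluded)`.
#' @export
utr3_density_comparison <- function(tracks_treated, tracks_untreated,
                                    models) {
  rows <- list()
  excluded <- 0L
  for (m in models) {
    if (m$cds_end >= m$length) { excluded <- excluded + 1L; next }
    span <- (m$cds_end + 1L):m$length
    len <- length(span)
    dt <- sum(tracks_treated[[m$transcript_id]][span]) / len
    du <- sum(tracks_untreated[[m$transcript_id]][span]) / len
    rows[[length(rows) + 1L]] <- data.frame(
      transcript_id = m$transcript_id, utr3_len = len,
      density_treated = dt, density_untreated = du, diff = dt - du,
      stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows)
         else data.frame(transcript_id = character(0), utr3_len = integer(0),
                         density_treated = numeric(0),
                         density_untreated = numeric(0), diff = numeric(0))
  list(table = tab,
       median_diff = if (nrow(tab)) stats::median(tab$diff) else NA_real_,
       fraction_increased = if (nrow(tab)) mean(tab$diff > 0) else NA_real_,
       n_excluded = excluded)
}

#' Metagene profile of ribosome density around stop codons
#'
#' For each transcript with positive CDS density, positional P-site counts
#' in a window around the stop codon's first base are normalised by that
#' transcript's CDS read density, then averaged position-wise across
#' transcripts. The profile is therefore invariant to per-transcript
#' sequencing depth.
#'
#' @param tracks named list of P-site tracks.
#' @param models list of [transcript_model()] objects.
#' @param window `c(upstream, downstream)` nt around the stop codon's first
#'   base (default 50 and 100).
#' @return data.frame with `rel_pos` (0 = first stop-codon base),
#'   `mean_density` and `n_transcripts` contributing per position.
#' @export
metagene_stop_profile <- function(tracks, models, window = c(50L, 100L)) {
  rel <- seq.int(-window[1], window[2])
  acc <- matrix(NA_real_, nrow = length(models), ncol = length(rel))
  used <- 0L
  for (m in models) {
    track <- tracks[[m$transcript_id]]
    cds_len <- m$cds_end - m$cds_start
    dens <- sum(track[(m$cds_start + 1L):m$cds_end]) / cds_len
    if (!is.finite(dens) || dens <= 0) next
    used <- used + 1L
    stop_first <- m$cds_end - 3L           # 0-based first base of stop codon
    pos <- stop_first + rel                # 0-based positions
    ok <- pos >= 0L & pos < m$length
    acc[used, ok] <- track[pos[ok] + 1L] / dens
  }
  if (used == 0L)
    return(data.frame(rel_pos = integer(0), mean_density = numeric(0),
                      n_transcripts = integer(0)))
  acc <- acc[seq_len(used), , drop = FALSE]
  data.frame(rel_pos = rel,
             mean_density = colMeans(acc, na.rm = TRUE),
             n_transcripts = colSums(!is.na(acc)))
}

#' Shared and condition-specific readthrough events
#'
#' @param rrts_a,rrts_b RRTS tables ([rrts_table()]) for two conditions.
#' @return `list(shared, a_only, b_only, n_a, n_b, n_shared)` of
#'   transcript ids flagged `is_event`.
#' @export
compare_readthrough_events <- function(rrts_a, rrts_b) {
  ev_a <- rrts_a$transcript_id[rrts_a$is_event %in% TRUE]
  ev_b <- rrts_b$transcript_id[rrts_b$is_event %in% TRUE]
  list(shared = sort(intersect(ev_a, ev_b)),
       a_only = sort(setdiff(ev_a, ev_b)),
       b_only = sort(setdiff(ev_b, ev_a)),
       n_a = length(ev_a), n_b = length(ev_b),
       n_shared = length(intersect(ev_a, ev_b)))
}

#' Translation efficiency with inclusion criteria
#'
#' TE is reported as mean RNA-seq CPM over mean Ribo-seq CPM (the
#' orientation used throughout these analyses; flip with
#' `config$te_direction = "ribo_over_rna"`). A gene is included only when
#' (1) it is detected (count > 0) in every RNA and Ribo replicate, (2) its
#' RNA CPM is at least `te_min_rna_cpm` in every RNA replicate, and (3) its
#' Ribo raw count reaches `te_min_ribo_count` in every Ribo replicate.
#' Excluded genes carry the first failing reason code.
#'
#' @param rna_counts,ribo_counts RAW `count_matrix` objects over a shared
#'   gene universe (replicates as columns).
#' @param config a [pipeline_config()].
#' @return data.frame with `gene_id`, `rna_cpm`, `ribo_cpm`, `te`,
#'   `included`, `reason`.
#' @export
translation_efficiency <- function(rna_counts, ribo_counts,
                                   config = pipeline_config()) {
  genes <- intersect(rownames(rna_counts$counts), rownames(ribo_counts$counts))
  if (!length(genes)) stop("no shared genes between RNA and Ribo matrices")
  rna <- rna_counts$counts[genes, , drop = FALSE]
  ribo <- ribo_counts$counts[genes, , drop = FALSE]
  rna_cpm <- t(t(rna) * 1e6 / colSums(rna))
  ribo_cpm <- t(t(ribo) * 1e6 / colSums(ribo))

  detected <- rowSums(rna == 0) == 0 & rowSums(ribo == 0) == 0
  rna_ok <- apply(rna_cpm, 1, min) >= config$te_min_rna_cpm
  ribo_ok <- apply(ribo, 1, min) >= config$te_min_ribo_count

  reason <- rep("ok", length(genes))
  reason[!ribo_ok] <- "ribo_count"
  reason[!rna_ok] <- "rna_cpm"
  reason[!detected] <- "replicate"
  included <- detected & rna_ok & ribo_ok

  mr <- rowMeans(rna_cpm)
  mb <- rowMeans(ribo_cpm)
  te <- if (config$te_direction == "rna_over_ribo") mr / mb else mb / mr
  te[!included] <- NA_real_
  data.frame(gene_id = genes, rna_cpm = mr, ribo_cpm = mb, te = te,
             included = included, reason = reason,
             row.names = NULL, stringsAsFactors = FALSE)
}
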