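#' Transcript model with annotated CDS
#'
#' A transcript record in transcript space: the spliced sense-strand sequence
#' plus the CDS interval. All coordinates in this package are 0-based
#' half-open on the transcript; public tables carry 1-based positions in
#' columns named `pos_1based`. The CDS interval includes the stop codon, so
#' the stop codon occupies `cds_end - 3 .. cds_end`.
#'
#' @param transcript_id transcript identifier.
#' @param sequence DNA or RNA alphabet string; stored uppercased with U
#'   normalised to T.
#' @param cds_start,cds_end 0-based half-open CDS offsets; the length must be
#'   divisible by 3 and the interval must fit the sequence.
#' @param gene_id gene identifier (defaults to the transcript id).
#' @param anticodon,isodecoder_id optional tRNA annotations.
#'
#' @return a list with class `"transcript_model"`; `$stop_codon` holds the
#'   3-nt stop-codon sequence.
#' @export
transcript_model <- function(transcript_id, sequence, cds_start, cds_end,
                             gene_id = transcript_id,
                             anticodon = NULL, isodecoder_id = NULL) {
  sequence <- normalize_seq(sequence)
  n <- nchar(sequence)
  cds_start <- as.integer(cds_start)
  cds_end <- as.integer(cds_end)
  if (!(0L <= cds_start && cds_start < cds_end && cds_end <= n))
    stop("transcript ", transcript_id,
         ": CDS interval [", cds_start, ", ", cds_end,
         ") does not satisfy 0 <= start < end <= length(", n, ")")
  if ((cds_end - cds_start) %% 3L != 0L)
    stop("transcript ", transcript_id, ": CDS length not divisible by 3")
  structure(list(
    transcript_id = transcript_id,
    sequence = sequence,
    length = n,
    cds_start = cds_start,
    cds_end = cds_end,
    stop_codon = substr(sequence, cds_end - 2L, cds_end),
    gene_id = gene_id,
    anticodon = anticodon,
    isodecoder_id = isodecoder_id
  ), class = "transcript_model")
}

normalize_seq <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' Read transcript sequences from FASTA
#'
#' Sequences are uppercased and U is normalised to T so that a single DNA
#' alphabet is used everywhere; record order is preserved.
#'
#' @param path FASTA file path.
#' @return named character vector of sequences (names are the first
#'   whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) return(setNames(character(0), character(0)))
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids)))
    stop("FASTA record ", which(!nzchar(ids))[1], " has an empty header")
  if (any(nchar(seqs) == 0L))
    stop("FASTA record '", ids[which(nchar(seqs) == 0L)[1]],
         "' has an empty sequence")
  setNames(normalize_seq(seqs), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Read a per-site deletion count table
#'
#' Expects a TSV with columns `transcript_id`, `pos_1based`, `sample_id`,
#' `chemistry` (`PRAISE_PLUS`/`PRAISE_MINUS`), `treatment`
#' (`TREATED`/`UNTREATED`), `depth`, `deletions`. Positions are converted to
#' the internal 0-based convention; `deletions <= depth` is enforced.
#'
#' @param path TSV path.
#' @return data.frame with internal column `pos` (0-based).
#' @export
read_site_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("transcript_id", "pos_1based", "sample_id", "chemistry",
           "treatment", "depth", "deletions")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("site-count table is missing column(s): ", paste(miss, collapse = ", "))
  validate_site_counts(data.frame(
    transcript_id = as.character(df$transcript_id),
    pos = as.integer(df$pos_1based) - 1L,
    sample_id = as.character(df$sample_id),
    chemistry = as.character(df$chemistry),
    treatment = as.character(df$treatment),
    depth = as.integer(df$depth),
    deletions = as.integer(df$deletions),
    stringsAsFactors = FALSE
  ))
}

validate_site_counts <- function(df) {
  bad <- which(df$deletions > df$depth | df$deletions < 0L | df$depth < 0L)
  if (length(bad))
    stop("invalid site counts at row ", bad[1],
         ": deletions (", df$deletions[bad[1]],
         ") exceed depth (", df$depth[bad[1]], ") or are negative")
  badc <- which(!df$chemistry %in% c("PRAISE_PLUS", "PRAISE_MINUS"))
  if (length(badc))
    stop("row ", badc[1], ": unknown chemistry '", df$chemistry[badc[1]], "'")
  badt <- which(!df$treatment %in% c("TREATED", "UNTREATED"))
  if (length(badt))
    stop("row ", badt[1], ": unknown treatment '", df$treatment[badt[1]], "'")
  df
}

#' Write a site-count table (1-based positions)
#'
#' Inverse of [read_site_counts()]; round-trips bit-identically for valid
#' tables.
#'
#' @param df site-count data.frame with internal 0-based `pos`.
#' @param path output TSV path.
#' @export
write_site_counts <- function(df, path) {
  out <- data.frame(
    transcript_id = df$transcript_id,
    pos_1based = df$pos + 1L,
    sample_id = df$sample_id,
    chemistry = df$chemistry,
    treatment = df$treatment,
    depth = df$depth,
    deletions = df$deletions
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export intervals as BED6
#'
#' Items are written 0-based half-open in transcript space with strand `+`,
#' sorted by (transcript, start).
#'
#' @param items data.frame with columns `transcript_id`, `start`, `end`,
#'   `name`, `score`.
#' @param path output path.
#' @export
write_bed <- function(items, path) {
  req <- c("transcript_id", "start", "end", "name", "score")
  miss <- setdiff(req, names(items))
  if (length(miss))
    stop("BED export needs column(s): ", paste(miss, collapse = ", "))
  if (nrow(items) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  items <- items[order(items$transcript_id, items$start), , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t+",
                   items$transcript_id, as.integer(items$start),
                   as.integer(items$end), as.character(items$name),
                   as.character(items$score))
  writeLines(lines, path)
  invisible(path)
}

#' Count matrix container
#'
#' Thin wrapper over a numeric feature x sample matrix that tracks feature
#' lengths (needed for RPKM) and the normalization state.
#'
#' @param counts numeric matrix with rownames (features) and colnames
#'   (samples).
#' @param feature_lengths optional named vector of feature lengths in nt.
#' @param normalization one of `"RAW"`, `"CPM"`, `"RPKM"`, `"RPM"`.
#' @return a `count_matrix` object.
#' @export
count_matrix <- function(counts, feature_lengths = NULL,
                         normalization = "RAW") {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have feature rownames and sample colnames")
  if (any(counts < 0)) stop("counts must be non-negative")
  normalization <- match.arg(normalization, c("RAW", "CPM", "RPKM", "RPM"))
  if (normalization == "RAW" && any(counts != round(counts)))
    stop("RAW counts must be integers")
  if (!is.null(feature_lengths)) {
    if (is.null(names(feature_lengths)))
      stop("feature_lengths must be named")
    miss <- setdiff(rownames(counts), names(feature_lengths))
    if (length(miss))
      stop("feature_lengths missing for: ", paste(utils::head(miss, 3), collapse = ", "))
    feature_lengths <- feature_lengths[rownames(counts)]
  }
  structure(list(counts = counts, feature_lengths = feature_lengths,
                 normalization = normalization),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples [%s]\n",
              nrow(x$counts), ncol(x$counts), x$normalization))
  invisible(x)
}

#' Read a count matrix from TSV
#'
#' First column is the feature id; remaining columns are samples. An optional
#' `length` column supplies feature lengths.
#'
#' @param path TSV path.
#' @return a `count_matrix` with `normalization = "RAW"`.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(df[[1]])
  df <- df[-1]
  lens <- NULL
  if ("length" %in% names(df)) {
    lens <- setNames(as.numeric(df$length), ids)
    df <- df[setdiff(names(df), "length")]
  }
  m <- as.matrix(df)
  rownames(m) <- ids
  count_matrix(m, feature_lengths = lens)
}

#' Write a count matrix to TSV
#'
#' @param cm a `count_matrix`.
#' @param path output path.
#' @export
write_count_matrix <- function(cm, path) {
  df <- data.frame(feature_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE)
  if (!is.null(cm$feature_lengths))
    df$length <- cm$feature_lengths
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
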