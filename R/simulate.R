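#' Synthetic-data generators
#'
#' Every input the pipeline consumes can be generated with planted ground
#' truth, so all stages are testable without the deposited datasets. All
#' generators are deterministic given their arguments and `seed`; truth is
#' returned alongside the data, never re-derived from the files.
#'
#' @name synthetic_data
NULL

BASES <- c("A", "C", "G", "T")

#' Simulate a transcriptome with planted guide-complementary windows
#'
#' Background sequence is uniform over ACGT. Each planted copy of a 17-nt
#' guide-complementarity pattern carries exactly the requested number of
#' mismatches over the 15 scored positions (never at the central editable T,
#' position 8 1-based, nor at the degenerate N position 9), keeps a T at the
#' central position, and gets a random base at the N. Planted windows never
#' overlap.
#'
#' @param n_transcripts number of transcripts.
#' @param length_range length range (inclusive) for each transcript.
#' @param planted_motifs list of `list(pattern=, n_copies=, n_mismatches=)`;
#'   patterns are 17 nt with exactly one N.
#' @param seed integer seed.
#' @return `list(sequences = named character vector, truth = data.frame)`
#'   where truth has `transcript_id`, `start` (0-based window offset),
#'   `mismatches`, `window_seq`.
#' @export
sim_transcriptome <- function(n_transcripts, length_range,
                              planted_motifs = list(), seed = 1L) {
  set.seed(seed)
  lens <- if (length(length_range) == 1L) rep(length_range, n_transcripts)
          else sample(length_range[1]:length_range[2], n_transcripts, replace = TRUE)
  chars <- lapply(lens, function(L) sample(BASES, L, replace = TRUE))
  ids <- sprintf("tx%04d", seq_len(n_transcripts))
  names(chars) <- ids

  truth <- list()
  occupied <- lapply(lens, function(L) integer(0))  # occupied window starts (1-based)
  names(occupied) <- ids
  for (motif in planted_motifs) {
    pat <- parse_guide_pattern(motif$pattern)
    for (i in seq_len(motif$n_copies)) {
      placed <- FALSE
      for (attempt in 1:200) {
        tx <- sample(ids, 1L)
        L <- lens[match(tx, ids)]
        if (L < 17L) next
        s <- sample.int(L - 16L, 1L)  # 1-based window start
        occ <- occupied[[tx]]
        if (any(abs(occ - s) < 17L)) next
        win <- pat$chars
        # random base at the degenerate position
        win[pat$n_pos] <- sample(BASES, 1L)
        if (motif$n_mismatches > 0L) {
          mm_at <- sample(pat$scored, motif$n_mismatches)
          for (j in mm_at)
            win[j] <- sample(setdiff(BASES, pat$chars[j]), 1L)
        }
        chars[[tx]][s:(s + 16L)] <- win
        occupied[[tx]] <- c(occ, s)
        truth[[length(truth) + 1L]] <- data.frame(
          transcript_id = tx, start = s - 1L,
          mismatches = as.integer(motif$n_mismatches),
          window_seq = paste(win, collapse = ""),
          stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place a non-overlapping planted copy; ",
             "too many copies for the available windows")
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth)
           else data.frame(transcript_id = character(0), start = integer(0),
                           mismatches = integer(0), window_seq = character(0))
  # Background windows can collide with a planted copy's mismatch count by
  # chance; the scan is checked against the full truth plus brute force.
  list(sequences = vapply(chars, paste, "", collapse = ""),
       truth = truth[order(truth$transcript_id, truth$start), , drop = FALSE])
}

#' Simulate PRAISE-style deletion-signature counts
#'
#' Deletion counts are Binomial(depth, rate) independently per sample and
#' condition. PRAISE(+) treated/untreated use the per-site rates supplied;
#' both PRAISE(-) samples use the chemistry-independent background rate.
#'
#' @param sites data.frame with `transcript_id`, `pos` (0-based),
#'   `delta_plus_treated`, `delta_plus_untreated`.
#' @param background_minus deletion probability in PRAISE(-) libraries.
#' @param depth covering reads per site and sample.
#' @param seed integer seed.
#' @return site-count data.frame in the [read_site_counts()] layout
#'   (0-based `pos`).
#' @export
sim_praise_counts <- function(sites, background_minus, depth, seed = 1L) {
  stopifnot(all(sites$delta_plus_treated >= 0 & sites$delta_plus_treated <= 1),
            all(sites$delta_plus_untreated >= 0 & sites$delta_plus_untreated <= 1),
            background_minus >= 0, background_minus <= 1)
  set.seed(seed)
  n <- nrow(sites)
  cond <- data.frame(
    chemistry = rep(c("PRAISE_PLUS", "PRAISE_PLUS",
                      "PRAISE_MINUS", "PRAISE_MINUS"), each = n),
    treatment = rep(c("TREATED", "UNTREATED", "TREATED", "UNTREATED"),
                    each = n),
    stringsAsFactors = FALSE)
  rate <- c(sites$delta_plus_treated, sites$delta_plus_untreated,
            rep(background_minus, 2L * n))
  out <- data.frame(
    transcript_id = rep(sites$transcript_id, 4L),
    pos = rep(sites$pos, 4L),
    sample_id = paste0("s_", tolower(substr(cond$chemistry, 8L, 12L)), "_",
                       tolower(cond$treatment)),
    chemistry = cond$chemistry,
    treatment = cond$treatment,
    depth = rep(as.integer(depth), 4L * n),
    deletions = stats::rbinom(4L * n, size = depth, prob = rate),
    stringsAsFactors = FALSE)
  validate_site_counts(out)
}

#' Simulate UMI-tagged amplicon reads
#'
#' Each family shares a distinct 14-nt UMI. A `deletion_fraction_at_target`
#' share of families carries a 1-nt deletion at the target position in every
#' read of the family (editing is a molecule-level event, so it is shared by
#' the whole family). Substitution errors are i.i.d. per base at
#' `per_base_error`.
#'
#' @param n_families number of UMI families.
#' @param family_size_dist integer vector of possible family sizes, sampled
#'   uniformly (a single value gives fixed-size families).
#' @param consensus_seq unedited amplicon sequence.
#' @param per_base_error substitution probability per base, in \[0, 0.2\].
#' @param deletion_fraction_at_target fraction of families carrying the
#'   target deletion.
#' @param target_pos 0-based offset of the editable base in `consensus_seq`.
#' @param seed integer seed.
#' @return `list(reads = data.frame(read_id, umi, sequence), truth =
#'   data.frame(umi, size, has_deletion, true_consensus))`.
#' @export
sim_amplicon_reads <- function(n_families, family_size_dist, consensus_seq,
                               per_base_error, deletion_fraction_at_target,
                               target_pos, seed = 1L) {
  stopifnot(per_base_error >= 0, per_base_error <= 0.2,
            deletion_fraction_at_target >= 0, deletion_fraction_at_target <= 1)
  consensus_seq <- normalize_seq(consensus_seq)
  set.seed(seed)
  umis <- make_unique_umis(n_families)
  sizes <- if (length(family_size_dist) == 1L)
    rep(as.integer(family_size_dist), n_families)
  else sample(as.integer(family_size_dist), n_families, replace = TRUE)
  has_del <- stats::rbinom(n_families, 1L, deletion_fraction_at_target) == 1L
  del_seq <- paste0(substr(consensus_seq, 1L, target_pos),
                    substr(consensus_seq, target_pos + 2L,
                           nchar(consensus_seq)))
  true_cons <- ifelse(has_del, del_seq, consensus_seq)

  reads <- vector("list", n_families)
  for (i in seq_len(n_families)) {
    tmpl <- strsplit(true_cons[i], "")[[1]]
    fam <- character(sizes[i])
    for (r in seq_len(sizes[i])) {
      rc <- tmpl
      err <- stats::runif(length(rc)) < per_base_error
      if (any(err)) {
        idx <- which(err)
        rc[idx] <- vapply(rc[idx],
                          function(b) sample(setdiff(BASES, b), 1L), "")
      }
      fam[r] <- paste(rc, collapse = "")
    }
    reads[[i]] <- data.frame(
      read_id = sprintf("fam%05d_r%03d", i, seq_len(sizes[i])),
      umi = umis[i], sequence = fam, stringsAsFactors = FALSE)
  }
  list(reads = do.call(rbind, reads),
       truth = data.frame(umi = umis, size = sizes, has_deletion = has_del,
                          true_consensus = true_cons,
                          stringsAsFactors = FALSE))
}

make_unique_umis <- function(n, width = 14L) {
  umis <- character(0)
  while (length(umis) < n) {
    need <- n - length(umis)
    new <- vapply(seq_len(need + 16L),
                  function(i) paste(sample(BASES, width, replace = TRUE),
                                    collapse = ""), "")
    umis <- unique(c(umis, new))
  }
  umis[seq_len(n)]
}

#' Simulate per-position P-site coverage with planted readthrough
#'
#' Counts are Poisson per position: `cds_density` inside the CDS, `ratio *
#' cds_density` in the readthrough region (stop codon to transcript end) of
#' planted transcripts, and `noise` elsewhere. Matched gene-level RNA counts
#' are emitted for translation-efficiency analyses.
#'
#' @param transcripts list of [transcript_model()] objects.
#' @param cds_density expected P-site reads per CDS nt.
#' @param readthrough_set named numeric vector mapping transcript_id to the
#'   readthrough/CDS density ratio.
#' @param noise background density outside CDS and readthrough regions.
#' @param seed integer seed.
#' @return `list(tracks = named list of integer vectors, rna_counts = named
#'   integer vector, truth = data.frame(transcript_id, true_ratio))`.
#' @export
sim_ribo_coverage <- function(transcripts, cds_density, readthrough_set =
                                numeric(0), noise = 0, seed = 1L) {
  stopifnot(cds_density >= 0, noise >= 0, all(readthrough_set >= 0))
  set.seed(seed)
  tracks <- list()
  rna <- integer(0)
  truth <- data.frame(transcript_id = vapply(transcripts, `[[`, "",
                                             "transcript_id"),
                      true_ratio = 0, stringsAsFactors = FALSE)
  for (tm in transcripts) {
    lam <- rep(noise, tm$length)
    lam[(tm$cds_start + 1L):tm$cds_end] <- cds_density
    ratio <- readthrough_set[tm$transcript_id]
    if (!is.na(ratio) && length(ratio) && tm$cds_end < tm$length) {
      lam[(tm$cds_end + 1L):tm$length] <- ratio * cds_density
      truth$true_ratio[truth$transcript_id == tm$transcript_id] <- ratio
    }
    tracks[[tm$transcript_id]] <- stats::rpois(tm$length, lam)
    rna[tm$transcript_id] <- stats::rpois(1L, cds_density * tm$length)
  }
  list(tracks = tracks, rna_counts = rna, truth = truth)
}

#' Simulate a negative-binomial count matrix with planted fold changes
#'
#' Two groups (untreated, treated) with `n_replicates` samples each; counts
#' are NB with a common dispersion around per-feature means drawn log-normal.
#' Planted folds multiply the treated-group mean of the named features.
#'
#' @param n_features number of features.
#' @param n_replicates samples per group.
#' @param nb_dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param planted_fold named numeric vector feature_id -> fold.
#' @param base_mean geometric-mean expected count per feature.
#' @param feature_ids optional feature names (default f0001..).
#' @param seed integer seed.
#' @return `list(cm = count_matrix, treated = colnames, untreated = colnames,
#'   truth = data.frame(feature_id, true_log2fc))`.
#' @export
sim_count_matrix <- function(n_features, n_replicates = 2L, nb_dispersion = 0.01,
                             planted_fold = numeric(0), base_mean = 500,
                             feature_ids = NULL, seed = 1L) {
  stopifnot(nb_dispersion > 0)
  set.seed(seed)
  ids <- if (is.null(feature_ids)) sprintf("f%04d", seq_len(n_features))
         else feature_ids
  stopifnot(length(ids) == n_features)
  mu <- base_mean * exp(stats::rnorm(n_features, 0, 0.5))
  names(mu) <- ids
  fold <- setNames(rep(1, n_features), ids)
  if (length(planted_fold)) {
    miss <- setdiff(names(planted_fold), ids)
    if (length(miss)) stop("planted_fold names not in feature set: ",
                           paste(miss, collapse = ", "))
    fold[names(planted_fold)] <- planted_fold
  }
  untreated <- sapply(seq_len(n_replicates), function(i)
    stats::rnbinom(n_features, mu = mu, size = 1 / nb_dispersion))
  treated <- sapply(seq_len(n_replicates), function(i)
    stats::rnbinom(n_features, mu = mu * fold, size = 1 / nb_dispersion))
  m <- cbind(untreated, treated)
  rownames(m) <- ids
  colnames(m) <- c(paste0("untreated_", seq_len(n_replicates)),
                   paste0("treated_", seq_len(n_replicates)))
  list(cm = count_matrix(m),
       treated = paste0("treated_", seq_len(n_replicates)),
       untreated = paste0("untreated_", seq_len(n_replicates)),
       truth = data.frame(feature_id = ids, true_log2fc = log2(fold),
                          row.names = NULL, stringsAsFactors = FALSE))
}

#' Simulate a tRNA count matrix with an introduced near-cognate tRNA
#'
#' Builds a tRNA annotation (amino acid, anticodon, isodecoder family)
#' including the engineered suppressor feature `R-TCT-1-1`, and plants a fold
#' change on it alone, emulating episomal expression of the near-cognate tRNA
#' against a stable endogenous pool.
#'
#' @param n_per_family isodecoders per anticodon family.
#' @param planted_fold fold change planted on `R-TCT-1-1` (treated group).
#' @param n_replicates samples per group.
#' @param nb_dispersion NB dispersion.
#' @param base_mean expected counts per tRNA feature.
#' @param seed integer seed.
#' @return as [sim_count_matrix()], plus `annotation` with `feature_id`,
#'   `amino_acid`, `anticodon`, `isodecoder_id`.
#' @export
sim_trna_matrix <- function(n_per_family = 2L, planted_fold = 1.5,
                            n_replicates = 2L, nb_dispersion = 5e-4,
                            base_mean = 5000, seed = 1L) {
  families <- list(
    R = c("ACG", "CCG", "CCT", "TCG", "TCT"),
    L = c("AAG", "CAA", "CAG", "TAA", "TAG"),
    S = c("AGA", "CGA", "GCT", "TGA"),
    G = c("GCC", "CCC", "TCC"),
    A = c("AGC", "CGC", "TGC"),
    K = c("CTT", "TTT"),
    E = c("CTC", "TTC"),
    V = c("AAC", "CAC", "TAC"))
  ann <- do.call(rbind, lapply(names(families), function(aa) {
    do.call(rbind, lapply(families[[aa]], function(ac) {
      data.frame(
        feature_id = sprintf("%s-%s-%d-1", aa, ac, seq_len(n_per_family)),
        amino_acid = aa, anticodon = ac,
        isodecoder_id = sprintf("%s-%s-%d", aa, ac, seq_len(n_per_family)),
        stringsAsFactors = FALSE)
    }))
  }))
  sim <- sim_count_matrix(
    n_features = nrow(ann), n_replicates = n_replicates,
    nb_dispersion = nb_dispersion,
    planted_fold = setNames(planted_fold, "R-TCT-1-1"),
    base_mean = base_mean, feature_ids = ann$feature_id, seed = seed)
  sim$annotation <- ann
  sim
}

#' Simulate a peptide abundance table for PTC-residue analysis
#'
#' Peptides spanning the premature stop are labelled with the residue
#' incorporated at the PTC position; residues are drawn from `residue_mixture`
#' and precursor abundances are log-normal around `abundance_scale` in two
#' replicates. PSM counts are >= 2 except for a small fraction of singletons,
#' which downstream analysis must discard.
#'
#' @param residue_mixture named fractions over one-letter amino-acid codes;
#'   must sum to 1 within 1e-9.
#' @param n_peptides number of peptides.
#' @param abundance_scale median precursor intensity.
#' @param singleton_fraction fraction of peptides with psm_count = 1.
#' @param seed integer seed.
#' @return `list(peptides = data.frame(peptide_id, ptc_residue, psm_count,
#'   abundance_rep1, abundance_rep2), truth = residue_mixture)`.
#' @export
sim_peptide_table <- function(residue_mixture, n_peptides,
                              abundance_scale = 1e6,
                              singleton_fraction = 0.05, seed = 1L) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (!all(names(residue_mixture) %in% aa))
    stop("residue_mixture names must be one-letter amino-acid codes")
  if (abs(sum(residue_mixture) - 1) > 1e-9)
    stop("residue_mixture fractions must sum to 1")
  set.seed(seed)
  res <- sample(names(residue_mixture), n_peptides, replace = TRUE,
                prob = residue_mixture)
  psm <- 1L + stats::rpois(n_peptides, 3L)
  psm[stats::runif(n_peptides) < singleton_fraction] <- 1L
  ab1 <- stats::rlnorm(n_peptides, log(abundance_scale), 0.8)
  ab2 <- ab1 * stats::rlnorm(n_peptides, 0, 0.15)
  list(peptides = data.frame(
    peptide_id = sprintf("pep%05d", seq_len(n_peptides)),
    ptc_residue = res, psm_count = psm,
    abundance_rep1 = ab1, abundance_rep2 = ab2,
    stringsAsFactors = FALSE),
    truth = residue_mixture)
}
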