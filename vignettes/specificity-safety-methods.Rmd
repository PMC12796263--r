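---
title: "Methods: quantifying the specificity and safety of pseudouridine-directed PTC readthrough"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the specificity and safety of pseudouridine-directed PTC readthrough}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psiedit)
```

## The problem

Guide-snoRNA pseudouridine editors suppress a premature termination codon
(PTC) by isomerising its uridine to pseudouridine (Ψ), which lets the
ribosome read through the stop; a co-delivered near-cognate suppressor tRNA
decodes the ΨGA codon as arginine. Before such an editor can be trusted,
several orthogonal sequencing readouts must agree that it does only what it
is meant to do:

* **Ψ stoichiometry and off-target calling.** Bisulfite-style deletion
  chemistry converts each Ψ into a deletion signature, so the per-site
  modification level is the deletion rate δ = deletions / covering reads.
  Chemically treated, "PRAISE(+)", libraries carry the signal; untreated
  PRAISE(−) libraries control for chemistry-independent deletions.
* **Guide complementarity.** Off-targets arise through partial base pairing
  with the guide, so candidate loci can be predicted by scanning the
  transcriptome for near-matches to the guide-complementary pattern.
* **Amplicon editing efficiency.** At the target itself, UMI-tagged deep
  amplicon sequencing gives a per-molecule editing rate once reads are
  collapsed to one consensus per original molecule.
* **Translation safety.** Ribosome profiling quantifies whether readthrough
  leaks onto normal stop codons (ribosome readthrough score, 3'UTR footprint
  density, stop-codon metagene) or shifts translation efficiency.
* **Expression stability.** RNA-seq and tRNA-seq abundances should stay put
  apart from the introduced suppressor tRNA; peptide mass spectrometry
  should show a single dominant residue at the repaired position.

Every stage is implemented here over synthetic inputs with planted ground
truth, so the whole pipeline is testable end to end without any deposited
dataset.

## Site calling model

For each candidate uridine the pipeline pools replicate counts per
condition (summing numerators and denominators — the conservative default;
per-replicate calling would test each pair separately and is a
straightforward extension of the same primitives), computes the four
condition rates, and applies four criteria:

1. |δ⁺(treated) − δ⁺(untreated)| > 5% — the editor changed the site;
2. every PRAISE(−) rate < 5% — the signal is chemistry-dependent, not an
   alignment artefact;
3. Fisher exact p < 0.005 between treated PRAISE(+) and treated PRAISE(−)
   deletion counts;
4. δ⁺(treated) − δ⁺(untreated) > 10% — the change is an *increase* of
   meaningful size.

Criterion 1 is read as an absolute difference and criterion 4 as a signed
increase: that is the only reading under which the two printed thresholds
(5% and 10%) are both load-bearing, and it makes the pair robust to sites
that *lose* modification. The "contingency table test" is implemented as the
two-sided Fisher exact test because PRAISE(−) deletion counts are typically
tiny and the exact test remains valid there; a chi-squared alternative is
config-exposed (`contingency_method = "chisq"`) for very deep data. The
implementation enumerates the hypergeometric distribution directly (with the
conventional 1 + 1e-7 tie tolerance); the test suite checks it against both
`stats::fisher.test` and an independent binomial-coefficient enumeration on
every 2×2 table with margins up to 50.

Endogenous Ψ sites are called from the untreated pair alone: δ⁺ ≥ 5%,
PRAISE(−) < 5%, p < 0.005. These thresholds are defaults inherited from
common practice with this chemistry, deliberately config-exposed rather than
asserted; sensitivity to them is trivial to explore through
`pipeline_config()`.

A deletion rate is *undefined* below `min_depth = 20` covering reads
(binomial SE at δ = 0.3 is ≈ 0.10 there; anything shallower is noise), and a
locus missing any required condition is reported with status `"incomplete"`
rather than dropped — silent loss of loci is the classic failure mode of
such filters.

## Guide-complementarity scan

The guide pairs with a 17-nt window; the editable T sits at pattern position
8 (1-based) and the following position is degenerate (N). A window matches
when the base opposite the editable position is T and at most
`max_mismatches = 3` of the remaining 15 scored positions disagree. The
pattern's published form brackets the degenerate base
(`AATTTACT[ATCG]AACAGAGG`), which fixes the indexing: the "central" T can
only be the base before the N. All windows are reported without merging
(the report-all contract of an exhaustive aligner), sorted by locus, and
ranked by mismatch count with a deterministic (transcript, start) tie-break
for the top-k report. Only the sense strand is scanned: the guide pairs with
the mRNA itself, so the reverse complement is biologically irrelevant here.

## UMI consensus and amplicon editing rate

Reads are grouped by exact 14-nt UMI match (no directional clustering — UMI
errors are not corrected, matching the described protocol); families under
3 reads are discarded. The consensus of a family is, by default, the
per-position majority over its reads (`consensus_mode = "column"`), with
ties broken lexicographically so the result is independent of read order.
The alternative reading of "most consensus sequence" — the modal whole
read — is implemented and selectable (`consensus_mode = "modal"`), but it is
not the default for a quantitative reason: with per-base error ε and read
length L, a read is error-free with probability (1−ε)^L ≈ 0.37 at ε = 1%
and L = 100, so a 3-read family usually contains no two identical correct
reads and modal selection degenerates into a tie-break. Column majority
fails only when two reads err at the same position, which keeps small
families informative (measured ≥ 99% family-level accuracy at ε = 1% in the
test suite).

Retained consensi are globally aligned to the amplicon reference
(gap-affine, Biostrings), substitutions and deletions scored separately: a
consensus with more than 2 substitutions is discarded, while a deletion —
the editing signal itself — is never counted as a mismatch. A deletion is
credited to the target if it falls anywhere within the homopolymer run
containing the target base, since deleting any base of a run yields the same
molecule and aligners place such gaps arbitrarily within the run. The target
deletion rate is then the fraction of retained consensi carrying the
deletion — a per-molecule analogue of the PRAISE stoichiometry.

## Ribosome profiling metrics

P-sites are placed at the footprint 5' end + 12 nt by default, with a
per-length offset table accepted for data where offsets were estimated from
frame periodicity (offset estimation itself is out of scope; footprints
outside 26–34 nt are dropped). The ribosome readthrough score of a
transcript is

RRTS = (P-site density from the first nt after the annotated stop to the
next in-frame stop codon, or the transcript end) / (P-site density in the
CDS),

undefined when the CDS has fewer than 20 P-site reads or no 3'UTR exists.
A transcript is a *readthrough event* when RRTS > 0.01; both the threshold
and the coverage floor are config-exposed defaults chosen here (the event
counts this metric is known for were published without the thresholds
behind them). The stop-codon metagene averages per-transcript tracks
normalised by each transcript's own CDS density over a −50..+100 nt window
around the stop, which makes the profile exactly invariant to
per-transcript depth. Translation efficiency is reported as mean RNA CPM /
mean Ribo CPM — the orientation as printed in the analyses this package
reproduces, the inverse of the older convention; `te_direction` flips it. A
gene enters the TE analysis only if detected in every replicate of both
assays, has RNA CPM ≥ 1 in every RNA replicate, and at least 20 raw
Ribo-seq reads in every Ribo replicate (the per-sample reading of the
count rule; the criterion is evaluated per replicate because "detected in a
sample" is a per-library property).

## Abundance stability

CPM/RPM divide by the column sum times 10⁶ (columns then sum to exactly
10⁶); RPKM further divides by feature length in kb. The
replicate-reproducibility filter removes features with
|log2((rep1 + ε)/(rep2 + ε))| > 1 on **raw counts** (the ratio is scale-free,
so raw vs normalised only matters through the pseudocount; raw counts keep
the filter independent of the normalisation step that follows it). The
printed form of the rule is one-sided; taken literally it would keep
features where replicate 2 vastly exceeds replicate 1, an asymmetry with no
possible design rationale, so the absolute value is the default and the
literal signed mode is available (`rep_filter_signed = TRUE`).
Between-condition agreement is a two-sided Pearson correlation on
log2-transformed mean abundances, optionally restricted to a named panel
(e.g. inflammatory factors). All log transforms of counts use pseudocount
ε = 0.5.

tRNA counts are summed within a group (transcript, anticodon family, or
isodecoder) *before* RPM normalisation, and the group fold change is the
log2 ratio of treated to untreated mean RPM. The expected signature of a
well-behaved suppressor-tRNA delivery is a fold change of ~1.5 confined to
the introduced isodecoder, with anticodon-level groups flat — which is
exactly what the planted-truth recovery tests assert.

## PTC-residue incorporation

From the peptide table (search-engine output over a database carrying all
20 residues at the PTC position), peptides with PSM ≤ 1 are discarded; the
incorporation fraction of residue X in a replicate is the summed precursor
abundance of retained X-peptides over total retained abundance. Replicates
are summarised as the mean of per-replicate fractions (matching how
two-replicate incorporation bars are reported); pooling abundances first is
available (`mode = "pooled"`) — on balanced replicates the two coincide.
Fractions always sum to 1 and are exactly scale-invariant.

## Synthetic data: what it emulates, and what it does not

The generators produce counts at the level each estimator consumes —
binomial deletions at planted δ per condition, Poisson positional coverage,
negative-binomial feature counts, multinomial PTC residues — plus literal
UMI-tagged reads for the amplicon stage, which is the only stage that needs
reads. Study conditions are fixed in the generator defaults and in the
analysis scripts: site depth 1000 with PRAISE(−) background 1%; planted
off-targets at δ 0.30 vs 0.02 among nulls at 0.02; 17-nt guide windows
planted at exact Hamming distances 0–3; amplicon length 120 nt, family
sizes uniform on 3..15, 1% per-base error, 25% of molecules edited; CDS
density 10 reads/nt (10⁴ CDS reads) for RRTS recovery; tRNA anticodon
groups at 10⁴ counts/sample with NB dispersion 5 × 10⁻⁴ (deep tRNA-seq of
pooled tissue behaves near-technically); a 99.98% : 0.02% arginine :
tryptophan mixture at the PTC.

Real data differ in ways these models deliberately ignore: sequence-context
dependence of the deletion chemistry, alignment artefacts around indels,
UMI collisions and polymerase jackpots, platform error profiles, periodicity
and ramp structure in ribosome footprints, and biological replicate
variability beyond a single dispersion parameter. Passing the recovery
tests therefore certifies the *estimators and filters* — that each
computation extracts what was planted, at the stated depths and noise
levels — not that any particular laboratory dataset will behave as cleanly.

## Numerical choices and degenerate inputs

* Fisher p-values use direct hypergeometric enumeration with the standard
  relative tie tolerance 1 + 1e-7; zero-depth tables are an error, not a
  p-value.
* Undefined is a value, not an error, wherever the data can legitimately be
  too shallow (deletion rates below `min_depth`, RRTS without coverage or
  3'UTR, amplicon rate with nothing retained); every undefined value
  carries a reason.
* Ties everywhere (consensus candidates, ranked guide matches) break
  lexicographically so all outputs are permutation-invariant and
  reproducible.
* Empty inputs return empty, correctly-typed tables (scan of a short
  transcript, BED export of nothing, metagene of no transcripts).
* All generators are deterministic given (arguments, seed); planted truth
  is returned alongside the data and is never re-derived from the files.

## Problem sizes

The bundled analysis scripts and the test suite run on deliberately small
instances — a 10-transcript × ~10 kb transcriptome, ~500–1000 candidate
sites at depth 1000, 400–1000 UMI families, 20 transcripts of ribosome
coverage, a 78-feature tRNA pool, and 2 × 10⁴–5 × 10⁴ peptides — sizes at
which every planted parameter is recoverable with comfortable margin while
a complete end-to-end run stays in the minutes range on one core. All
estimators are linear (or for the scan, linear × 17) in their input sizes,
so scaling to transcriptome-wide data is a matter of runtime, not of
method.

## Known limitations

* The scanner scores plain Hamming complementarity; it does not model
  duplex thermodynamics or snoRNA structure, so its ranking is a candidate
  list, not an affinity prediction.
* The off-target caller assumes the four conditions come from the same
  underlying locus coverage; it does not model mapping bias differences
  between PRAISE(+) and PRAISE(−) libraries.
* Consensus building assumes substitution-dominated read error; reads with
  spurious indels are handled only at the alignment-filter stage
  (flagged unalignable), not repaired.
* TE uses mean CPM over replicates with hard inclusion cutoffs; no
  shrinkage or uncertainty propagation is attempted, matching the simple
  ratio definition it implements.
* P-site offsets are fixed or user-supplied, never estimated.
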