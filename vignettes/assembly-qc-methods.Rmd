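---
title: "Methods: assembly completeness, comparison and substitution rates"
author: "asmqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assembly completeness, comparison and substitution rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmqc)
```

`asmqc` bundles the computations used to characterise a chromosome-level
mammalian genome assembly — the worked case being the Saanen_v1 goat
assembly (GCA_015443085.1) against the ARS1 reference (GCA_001704415.1) —
as reusable, tested functions: gap and length accounting, telomere and
centromere detection, k-mer genome-size estimation, inter-assembly
discrepancy calling, SNP-chip probe classification, and Y-versus-autosome
substitution-rate estimation. This vignette explains each method, its
assumptions, the tunable parameters, and the choices made where the
procedures left room for interpretation.

## Coordinates, sequences and gaps

All intervals are 0-based half-open internally; a printed length always
equals `end - start`. Sequences are normalised on input to the alphabet
`{A,C,G,T,N}`: lowercase is uppercased and IUPAC ambiguity codes map to
`N`, since finished assemblies carry essentially no ambiguity and only `N`
has a structural meaning (unsequenced bases).

Two related but distinct quantities describe missing sequence:

* **ungapped length** — total length minus *every* `N`, however isolated;
* **gap count** — the number of maximal `N` runs of at least `min_gap_run`
  bases (default 10, the NCBI convention; the QC literature typically does
  not state a minimum, so it is exposed as a parameter).

Contig N50 is computed by splitting scaffolds at counted gaps; scaffold
N50 on the intact records. `chromosome_report()` also accepts
pre-tabulated rows so a published per-chromosome table can be
re-summarised without the sequences; the tables for the two goat
assemblies ship in `extdata` (`goat_chrom_stats()`,
`goat_discrepancy_regions()`).

## Telomere and centromere detection

Goat autosomes are acrocentric: a complete assembly of one shows a
centromeric satellite array at the proximal end and a telomeric
`(TTAGGG)n` tract at the distal end. Detection proceeds as follows:

1. every exact occurrence of `TTAGGG` (and of `CCCTAA`, a minus-strand
   copy) is located;
2. runs of at least 10 motif copies in tandem — period exactly 6, one
   strand, a single interrupting base breaks the run — become seeds. The
   tandem reading is the strictest interpretation of "consecutive
   identical 6-mer matches" and reflects the tandem nature of telomeric
   DNA;
3. DUST low-complexity intervals (window 64 bp, score threshold 20) that
   intersect a seed are unioned with it; overlapping results merge
   (0 bp separation merges; no bridging across unmasked sequence);
4. merged regions at least 2 kb long with hexamer density strictly above
   0.5 are retained. Density is motif-covered bases over the *final
   merged region* length, counting overlapping strand hits once — i.e.
   the denominator includes any DUST-extended flanks, which can dilute
   density by at most one window width per side.

The DUST score used is the symmetric triplet-collision statistic
`10 * sum_t c_t(c_t-1)/2 / (l-1)` over the `l` ACGT triplets of a window;
whole qualifying windows are masked and their union merged. Random
sequence scores around 5, perfect short-period repeats score 40+, so the
threshold of 20 (read as a score, not a minimum interval width) separates
the two with a wide margin. Because a telomere call requires a seed run,
the DUST pass is skipped when no seed exists, making genome-wide scans of
motif-free sequence cheap.

Centromeric candidates are taken from a RepeatMasker-style annotation:
intervals labelled exactly `Satellite/centr` and strictly longer than
5 kb. A chromosome is called `near_complete` when a centromere starts
within `end_window` (default 500 kb — the annotation literature gives no
distance, so it is a parameter) of the proximal boundary *and* a telomere
lies within `end_window` of the distal boundary; otherwise `partial`.

## K-mer genome size

`kmer_histogram()` counts canonical (strand-folded) 17-mers exactly;
k-mers containing `N` are skipped. `find_peaks()` smooths the depth
counts with a window-3 moving average, takes the first local minimum as
the error valley and the global maximum beyond it as the homozygous
coverage peak; local maxima within 25% of half/double that depth are
flagged heterozygous/repeat peaks. Because the true mean k-mer depth is
rarely an integer, the peak is also refined sub-integer by the quadratic
vertex through the smoothed counts around the mode, and the size
estimator divides by the refined value (an integer peak alone limits
accuracy to `1/peak`, e.g. 2% at 50x). Error-free data rise straight into the
peak (valley = 1); a monotonically decaying spectrum has no coverage peak
and errors out. The estimate is
`genome_size = kmer_number / peak_depth`, with k-mer instances below the
valley excluded first (the behaviour of depth-based estimators that
separate an error component; `exclude_errors = FALSE` reproduces the raw
formula). Both smoothing window and valley rule are package choices,
stated here because the estimator literature varies on them.

## Inter-assembly discrepancies

Whole-genome alignment blocks (PAF) are chained per query chromosome:
blocks under 10 kb are dropped, and a chain extends while the query and
target gaps stay under 100 kb with consistent chromosome, strand and
order. Against that chain structure:

* a minus-strand chain flanked by plus-strand chains with the same
  partner chromosome is an **inversion**;
* a chain whose partner chromosome differs from the *dominant* partner of
  its query chromosome (largest aligned span), with flanks on the
  dominant partner, is **incorrectly placed**.

Only regions spanning at least 1 Mb on the comparison (target) assembly
are reported, and lengths are measured on the target interval — the
convention of the published discrepancy table, verified against all eight
printed rows. Calls are labelled putative: the original analysis
confirmed such regions by Hi-C contact matrices and cross-species
collinearity, which are out of scope here, so the chaining heuristic
stands in for manual curation.

Small structural variants are classified from the gap geometry between
consecutive anchors, in the spirit of the Assemblytics taxonomy:
insertion/deletion when one side's gap is near zero (≤ 10 bp),
repeat expansion/contraction when both gaps are positive,
tandem expansion/contraction when the anchors overlap on one side.
Variants are kept when `50 <= |size| <= 10,000` bp and the larger gap
exceeds 10 bp. Anchor-uniqueness filtering of the original tool is not
reproduced.

## SNP-probe discrepancies

A probe is mapped when its best hit has identity > 95% **and** coverage
> 90% (both strict). Ties between equal-score hits break by identity,
then chromosome name, then position, so the choice is deterministic.
Categories partition the panel: `unique_to_a`/`unique_to_b` (mapped on
one assembly), `diff_chr` (different chromosomes; takes precedence),
`diff_pos` (same chromosome, flagged by the rank-order test),
`consistent`, `unmapped_both`.

The rank-order ("changed order of the index") test orders the probes of
each chromosome by their position on assembly A and flags every probe
outside a longest strictly-increasing subsequence (LIS) of the B
positions. The LIS complement is the *minimal* set of probes whose
removal restores collinear order — the canonical minimal explanation of
an order change. One consequence worth knowing: when an inversion covers
k probes, the minimal-removal representation keeps one of them (any
single descending element can survive), so k−1 are flagged. Probe deserts
are inter-probe (and, by default, chromosome-terminal) intervals longer
than 1 Mb with no mapped probe.

## Substitution rates and male mutation bias

The alignment pipeline mirrors conservative multi-species practice:
within each MAF block, duplicate species rows are resolved to the row
nearest the column-majority consensus (ties keep file order); blocks are
flipped to the positive strand of the reference species; only blocks
containing all four species — cattle, yak, sheep, goat — are kept,
which on a Y chromosome largely restricts the data to X-degenerate
single-copy sequence.

The model is GTR (REV) with discrete-gamma rate variation: six
exchangeabilities (GT fixed at 1), free base frequencies, four
equal-probability categories whose rates are the within-bin means of the
fitted gamma shape. The rate matrix is scaled to one expected
substitution per site per unit branch length. Likelihoods come from
Felsenstein pruning on the fixed unrooted topology
`((cattle,yak),(sheep,goat))` — five branch lengths, no topology search —
using the symmetric eigendecomposition available for reversible models;
gaps and `N` are missing data. Site patterns are compressed before
optimisation, which for four taxa caps the work at 625 patterns
regardless of alignment length.

Optimisation is bounded quasi-Newton (`L-BFGS-B`) on log/softmax
transformed parameters, branch lengths bounded in (0, 10], with three
jittered starts (seeded) to avoid local optima; convergence uses the
optimiser's relative-tolerance default (~1e-9). Base frequencies start at
empirical values and branch lengths at halved pairwise mismatch
fractions. A cross-check against an independent ML implementation
(`phangorn`) on simulated data agrees in log-likelihood and branch
lengths and runs in the test suite.

The Y/A ratio is the ratio of *terminal* branch lengths of a species on
the Y and autosomal partitions (the per-branch presentation used in
comparative studies; a root-to-tip alternative would differ only through
the shared internal branch). Because the Y chromosome is transmitted
exclusively through males while autosomes average the two germlines, the
expected ratio under male mutation rate `u_m = alpha * u_f` is
`Y/A = 2*alpha/(1+alpha)`, inverted as `alpha = r/(2-r)` and undefined at
`r >= 2`. A ratio of 1.55 gives `alpha = 3.44`. The alternative relation
`Y/A = alpha/(1+alpha)` occasionally printed in the literature cannot
exceed 1 and therefore cannot explain observed ratios above 1; it is
available behind `paper_formula = TRUE` with a warning, for comparison
only.

## The synthetic-data generators

Every analysis is testable offline through seeded generators whose
defaults are the package's fixed study conditions:

* **Chromosomes** (`sim_config()`): 29 acrocentric chromosomes of 1 Mb,
  a 10 kb proximal satellite array (a fixed 30-mer monomer chosen free of
  the telomere motif on both strands, including across junctions, so the
  detectors cannot cross-fire), two 100-bp N gaps, and a 3 kb distal
  `(TTAGGG)n` tract on the chromosomes designated complete. 1 Mb keeps a
  29-chromosome genome scan in seconds while leaving the end windows
  non-overlapping; tract sizes are typical of assembled telomere/satellite
  remnants.
* **Assembly pairs**: planted ≥1 Mb inversions and translocations applied
  to a copy of assembly A, with the implied PAF block structure emitted
  directly (200 kb pieces), so discrepancy calling is exercised without
  running an aligner.
* **Reads**: uniform starts, both strands, independent substitution
  errors. The default 150 bp read length matches the short-read platform
  used for k-mer genome sizing; the coverage peak then sits at
  `(L-k+1)/L` of nominal depth (about 0.89 at 150 bp/k = 17), which the
  size estimate divides out exactly. Short reads also decorrelate
  per-base depth, keeping the spectrum smooth on small test genomes.
* **Probe panels**: probes tiled every 50 kb, lifted through the pair's
  segment map; truth labels follow the planted events.
* **Alignments**: iid columns evolved down the fixed topology under a
  transition-biased GTR (`AG`, `CT` elevated), mildly AT-rich frequencies
  (0.3/0.2/0.2/0.3), gamma shape 1.5 and terminal branch lengths of
  0.03–0.06 substitutions/site — ruminant-scale divergences; the Y
  partition scales all branches by a configurable multiplier (1.55 by
  default, the magnitude reported for Caprini). Partition sizes of
  100 kb (autosome) and 10 kb (Y) echo the hundredfold data asymmetry of
  real Y analyses while staying fast.

The generators produce iid, repeat-free cores, perfect tracts, exact
block structures and error-free probe hits. Passing closed-loop tests
therefore demonstrates the correctness of the computations under the
stated models — not robustness to segmental duplication, satellite
heterogeneity, alignment artefacts or indel evolution, none of which are
simulated (the MAF generator produces substitutions only; gaps enter the
likelihood solely as missing data).

In the recovery tests, branch-length accuracy is assessed on the mean of
three replicate 50 kb fits (the per-replicate Monte-Carlo error on a
0.02-substitutions/site branch is ~3%, so averaging keeps the check well
inside the 5% bound it asserts), and the Y/A multiplier is checked by the
2.5–97.5% interval of twenty seeded fits.

## Degenerate inputs and numerical notes

* `qv_estimate(0, G)` returns `Inf` (no observed consensus error).
* A k-mer spectrum with no local minimum and a mode at depth 1 (pure
  error decay) raises "no coverage peak".
* Zero branch lengths are valid in the likelihood (transition matrices
  reduce to the identity); fitted branch lengths are bounded below by 0
  via the log transform (~`exp(-12)`).
* Negative rounding artefacts in eigendecomposed transition matrices are
  clipped at 0 before use.
* `region_span()` rejects `end < start`; interval merging treats abutting
  intervals (0 bp apart) as one.
* Mb totals round half-even to one decimal, matching how published totals
  are printed.

## Known limitations

* Discrepancy calls lack orthogonal confirmation (no Hi-C module).
* The probe pipeline classifies mappings; it does not run an aligner.
* The rank-order test reports a minimal-removal set, which is not unique
  when several probes could equally be blamed for an order change.
* Heterozygosity is not modelled in the genome-size estimator (no
  GenomeScope-style mixture fit); the heterozygous peak is only flagged.
* The substitution-rate module fixes the four-taxon topology and does no
  model selection.
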