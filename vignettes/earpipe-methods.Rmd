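---
title: "Methods: models, parameters and design choices in earpipe"
author: "earpipe authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in earpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earpipe)
```

earpipe re-implements, at desk scale, the computational pipeline of a
combined small-RNA / degradome / microarray study of maize ear
development across four stages (I: growth-point elongation, II: spikelet
differentiation, III: floret primordium differentiation, IV: floret organ
differentiation). This vignette documents the models the package
implements, the tunable parameters, the synthetic-data generator that
stands in for sequencing data, and the design decisions taken where the
procedure left genuine choices open.

## Coordinate conventions and alphabets

All sequences are canonicalized to the RNA alphabet on ingest (T is
mapped to U); FASTA can be emitted as DNA on request. Genomic intervals
are standard Bioconductor `GRanges` (1-based, closed); BED input is
converted on read by `rtracklayer`. Transcript coordinates are 1-based
inclusive, the convention of the degradome literature; every profile and
target call states transcript coordinates in this frame. Transcript
models are read from transcript-space GFF3 (seqid = transcript id,
features `five_prime_UTR`/`CDS`/`three_prime_UTR`); projecting
genome-space annotation through exon chains is out of scope.

## Small-RNA census

Reads are collapsed to distinct tags inside a length window (default
18–30 nt, the read-length range of the sequenced libraries; the 18–25
preset used by some preprocessing pipelines is available via `maxLen`).
Mapping is perfect full-length matching on both strands — no mismatches —
delegated to `Biostrings::matchPDict`; a naive quadratic scan serves as
the test oracle. Each mapped tag is assigned exactly one annotation class
by a fixed precedence (rRNA > tRNA > snRNA > snoRNA > other_sRNA >
repeat > exon > unannotated). The precedence is not dictated by the
underlying procedure; structural RNAs are put first because their
annotation is the most reliable, and the order is configurable. Multi-hit
tags count once, by their highest-precedence overlap, since the published
class percentages are per distinct read; the census reports both
read-weighted and distinct-weighted fractions because the study text
mixes the two framings.

## Hairpin discovery

### Folding model

`foldHairpin` computes a minimum-energy nested structure by dynamic
programming over base-pair energies (GC = −3, AU = −2, GU = −1 kcal/mol;
hairpin loops ≥ 3 unpaired bases; no pseudoknots), with a deterministic
traceback that prefers the 5′-most pairing partner on ties. This is a
shape-level model, not full nearest-neighbor thermodynamics: every
downstream criterion depends only on hairpin geometry and an energy
threshold, and the pair-energy model keeps the whole pipeline
self-contained and exactly testable — the test suite checks the DP
against exhaustive enumeration of all nested structures on random
sequences. The folding entry point accepts an adapter-friendly surface
(sequence in, structure/MFE/pairs out) so an external thermodynamic
folder can be substituted as an oracle. One consequence matters for
pipeline design: under maximum-pairing energies, long (~270 nt) windows
of random sequence fold into dense, nearly saturated pair sets, so window
folds cannot localize a hairpin. Candidate localization therefore does
not rely on folding the full window (below).

### Excision and localization

For every seed tag hit (default: tags of 20–24 nt with ≥ 5 reads, not
classified as rRNA/tRNA/snRNA/snoRNA), two windows are excised: the tag
plus 250 nt upstream and the tag plus 250 nt downstream, clipped at
chromosome ends and strand-oriented. Within each window the miRNA* arm is
located by scanning for the best antisense match of the mature's first
L−2 bases (plain complementarity, mismatch 1 / G:U 0.5, no core
weighting; acceptance threshold 5), at least a loop's width away from the
tag. The candidate precursor is the span covering both arms plus a 12-nt
pad for the lower stem; when that span abuts a window edge it is
re-excised from the genome with 12 nt of extra room so the lower stem is
not truncated. The re-excised candidate is folded and kept; when both
windows yield candidates, the one satisfying the hairpin/duplex rules is
preferred, with MFE as the tie-break. (Preferring raw MFE alone is
biased: a longer random span always folds lower under a maximum-pairing
model.)

### Exclusion ledger

Folded candidates overlapping annotated exons or repeats are flagged, as
is any candidate with MFE above the stability threshold. The published
wording excludes loci "with free energy lower than −20 kcal/mol", which
read literally would discard the *most stable* hairpins; standard
pre-miRNA criteria retain ΔG ≤ −20 kcal/mol, and the package follows the
standard reading by default. `mfeLiteral = TRUE` flips the comparison for
anyone wanting the literal behavior. A candidate is excluded when any
flag is set, and the ledger summary reports counts per flag plus the
retained total, mirroring the locus accounting of the original analysis.

### Duplex detection and classification

The miRNA* is the stem segment pairing the mature, shifted to leave the
canonical Dicer signature of 2-nt 3′ overhangs on both duplex ends
(star span = partner(mature end − 2) … partner(mature start) + 2, with
unpaired mature bases bridged by linear extrapolation). A duplex is
accepted with at most 4 unpaired mature bases and no asymmetric bulge
over 2 nt; a mature spanning the terminal loop is a hard error. Star
abundance is the count of tags exactly matching the star segment and may
be zero — star read support is evidence, not a requirement.

Candidates surviving the ledger are first matched against a reference
mature set by edit distance (threshold 3, the tolerance at which family
paralogs typically differ; ties go to the lexicographically smallest
family label). The packaged reference (`referenceMature()`) is a
synthetic stand-in of family consensus sequences for offline testing, not
a database export — swap in a real mature FASTA for production use.
Unmatched candidates are classified by deterministic rules replacing a
trained pre-miRNA classifier: `not_hairpin` when no single stem holds
≥ 60% of the structure's pairs or a stem arm is shorter than the mature;
`pseudo` when hairpin-shaped but shorter than 60 nt or failing the duplex
rules; `novel` otherwise. Stems are pair runs grouped with a 4-nt bulge
tolerance. Identical mature sequences from multiple loci are merged into
one record with pooled loci; the abundance is the shared tag count, not
multiplied by the locus number, and same-family records with distinct
sequences receive a/b/… suffixes.

## Degradome target calling

Tags (20 nt; 21 accepted via `widths`) are placed on transcripts by exact
sense-strand matching. Repeat normalization divides each tag's count by
its total number of placements, so summed normalized abundance equals
summed placed raw counts — an invariant the tests enforce. For every
occupied position s, every guide is scored with nt 10 constrained to pair
s; the scoring scheme is the standard plant-target penalty table
(mismatch 1, G:U wobble 0.5, gap 1, at most one gap, penalties doubled at
miRNA positions 2–13, cutoff 7). These constants are configuration, not
hard-coded: the original analysis delegates them to its cited pipeline
without printing the rules. The "30-sequence tags" window of the
published methods is interpreted as 15 nt upstream of the tag's 5′ end
concatenated with the first 15 nt of the tag; the full constrained
placement is equivalent for gap-free sites, and near-threshold sites are
re-scored with the single-gap alignment. ta-siRNA guides are treated
identically to miRNAs — the caller accepts any 20–24-nt guide set.

Categories follow the five-tier degradome convention, computed over the
transcript's *occupied* positions (raw ≥ 1): category 4 when the site has
a single raw read (checked first); else 0 for a unique normalized
maximum, 1 for a tied maximum, 2 for above the median, 3 for at or below
the median. Whether the median includes zero-read positions is unstated
in the source; occupied-only is used because it is transcript-length
independent and consistent with the fractional abundances visible in the
printed tables. When every occupied position ties, the maximum tests win
(category 0/1, not 3). A site with no raw signal is reported as
no-signal, distinct from category 3. Categories 0–3 are invariant to
rescaling normalized abundance; category 4 depends only on the raw count.
Cross-stage merging emits one row per (guide, gene) with per-stage
"abundance (category)" cells from the best-supported site, and gene-level
region labels join distinct transcript labels with "/".

## Differential expression

Microarray-style intensities are log2-transformed and median-centered per
sample by default (the vendor normalization of the original assay is
unprinted; passthrough is available). Per probe, a one-way ANOVA across
stages computes F = MS_between/MS_within on (k−1, N−k) degrees of
freedom; probes with p < α (default 0.01) are DE. For DE probes the three
adjacent-stage contrasts are tested by Fisher's LSD: two-sided t tests on
the pooled within-stage variance with N−k df at the same α. Probes with
zero within-stage variance are flagged degenerate (p = 0 when means
differ; identical values everywhere are not DE). No multiple-testing
correction is applied by default because the original calls are raw
per-probe p < 0.01 decisions; a Benjamini–Hochberg switch exists. The
family roll-up uses the any-member rule (a family is DE when any member
probe is); the mean-of-members alternative is obtained by averaging
member probes before testing. The implementation is vectorized closed-form
arithmetic, verified against `anova(lm(...))` to |Δp| < 1e−10, and its
null calibration (DE fraction ≈ α on null probes) is part of the
acceptance checks.

## The synthetic-data generator

The generator defines the package's standard study conditions
(`simConfig` defaults): a 100-kb two-chromosome genome, 30 planted miRNA
precursors, 30 background loci per annotation class, 5×10⁴ small-RNA
reads with a 100:1 mature:star ratio and 30% of reads from planted loci,
1–2-nt end jitter on 10% of planted reads, 100 target transcripts of
600 nt (5′-UTR 15%, CDS 60%, 3′-UTR 25%) each carrying one planted
cleavage site, a 10:1 degradome signal:background ratio over a background
of mean count 2 occupying 15% of positions with exponential 3′ decay, and
a 4-stage × 4-replicate expression matrix of 200 probes with 20 planted
stage effects of 2 log2 units over noise of SD 0.5. The per-stage read
depth is a free parameter (only pooled totals were published); the
background read-length distribution is mode 24 nt with secondary 21/22-nt
modes, echoing the published size distribution qualitatively, and the
planted mature lengths follow the 20/21/22-nt mix of the printed novel
miRNAs. These sizes keep the full test suite and the acceptance script in
the minutes range on one CPU while leaving planted/background
discrimination non-trivial.

Precursors are built duplex-first — mature, shifted complement star with
planted G:U wobbles and 2-nt 3′ overhangs, an 8–15-nt loop, a perfectly
paired 10-nt lower stem — so foldability is guaranteed by construction
rather than by rejection-sampling random sequence; each precursor is then
certified against the package's own discovery rules (fold, duplex,
novelty, star identity) before being embedded, and re-drawn if
certification fails. Cleavage sites are planted as exact reverse
complements of the mature with the site coordinate opposite miRNA nt 10;
degradome tags are exact 20-nt transcript substrings. Counts are
Poisson-sampled around expectations unless `exactCounts = TRUE`.

What the generator does *not* emulate: sequencing errors beyond end
jitter, adapter artifacts, quality scores, expression-dependent ligation
bias in degradome libraries, paralogous gene families with near-identical
target sites, and genome-scale repeat structure. Passing the
planted-truth recovery checks therefore demonstrates the pipeline's
correctness on data satisfying its assumptions, not its performance on a
real 10⁷-read library; the published genome-scale counts are explicitly
not reproduction targets.

## Numerical choices and degenerate inputs

Energy ties in the fold DP are resolved toward the 5′-most partner;
floating-point comparisons in the DP use a 1e−9 tolerance (energies are
multiples of 0.5, so this is exact in practice). Category ties on the
normalized maximum use the same tolerance. Empty inputs return empty,
well-typed results (empty tag lists, empty profiles error only where the
operation is meaningless, e.g. a t-plot of an empty profile). Windows
clipped at chromosome or transcript ends are processed at their reduced
length; sub-guide-length windows are skipped. The discovery seed filter
(count ≥ 5, 20–24 nt) reflects how candidate lists are built from
abundant reads and bounds runtime on background-heavy libraries; both are
arguments.

## Known limitations

- The pair-energy fold model ranks structures by pairing capacity, not
  thermodynamics; MFE values are comparable within the model only, and
  the −20 kcal/mol ledger threshold should be re-calibrated if a
  thermodynamic folder is plugged in.
- Known-family assignment is global edit distance, not seed-region-aware
  alignment; at threshold 3 it approximates family-naming tolerance but
  will not resolve families that differ mainly outside the seed.
- The single-gap target alignment enumerates gaps exhaustively; longer
  indels are not modeled (consistent with the penalty scheme's ≤ 1 gap).
- The expression module assumes a balanced stage × replicate design;
  unbalanced designs error rather than reweight.
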