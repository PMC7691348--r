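---
title: "UMI-linked consensus calling: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{UMI-linked consensus calling: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umilink)
```

## The problem

Directed-evolution libraries contain gene variants that differ by only a
handful of point mutations. Long-read single-molecule platforms can read a
whole gene in one pass, but at 85-95% per-base accuracy a raw read cannot be
assigned to its template when candidate templates differ by one or two bases,
so naive consensus polishing is impossible. The remedy implemented here is a
molecular one carried through informatically: every template molecule is
tagged with a unique molecular identifier (UMI) — a fully random 50-mer —
before amplification. Reads sharing a UMI descend from one molecule, so
clustering reads by UMI similarity reconstructs per-molecule read bundles
from which an accurate consensus can be called, even in a pool of
near-identical sequences.

`umilink` implements the full computational workflow: a ground-truthed
simulator of epPCR libraries and noisy long reads; UMI extraction and greedy
clustering; base-space pileup consensus with support filters; and the
downstream evolutionary analyses (round demultiplexing, variant
deduplication, similarity networks, founder variants, positional enrichment,
epistasis classification).

## The simulator: what it emulates, and what it does not

The generator's defaults are the package's study conditions:

* **Mutation load.** Each library member carries a Poisson-distributed
  number of substitutions, mean 3.5 per gene — a typical load for one round
  of Mutazyme-style error-prone PCR. Positions are uniform without
  replacement over the gene; the alternative base is uniform over the three
  non-reference bases. An optional transition/transversion weighting is
  deliberately *not* the default: only the aggregate rate is treated as
  known, so the simplest unbiased model is used.
* **Construct layout.** `[barcode][gene][probe][UMI]`, with a 24-nt round
  barcode, a constant 20-nt probe anchoring the UMI, and a 50-nt random UMI.
  The exact published layout of such constructs varies; the layout here is
  fixed, documented, and configurable.
* **Read errors.** Each base is independently substituted (6%), deleted
  (2%), or followed by a one-base insertion (2%) — a 10% total error rate,
  i.e. 90% accuracy, the middle of the 85-95% regime of current nanopore
  basecalls. Strand is uniform; reverse reads are reverse complements.

The error process is i.i.d. per base. Real nanopore errors are not: they
concentrate in homopolymers and can be systematic in one read direction.
The filters retain the defences that matter against those artifacts (the
per-strand support filter, left-aligned indel normalisation so homopolymer
deletions aggregate into one candidate), but a passing simulation does not
certify performance on real signal-level artefacts — it certifies the
pipeline logic, the filter semantics and the statistical behaviour of
consensus under the stated error regime. That is also why the accuracy
figures the test-bench reports are *simulation analogs* of the published
values, not reproductions of measurements on Sanger-validated data.

## UMI clustering

UMIs are located by local alignment of the constant probe (both
orientations) and taking the bases immediately after the probe hit;
extractions failing an anchor-score floor (0.7 x match x probe length) or
truncated by more than 5 nt are excluded and counted. Scoring is
Smith-Waterman with affine gaps, defaults match +1, mismatch -1, gap open
-1, gap extend -1 (a gap of length *g* scores `gap_open + g*gap_extend`).
These values are deliberately edit-like so a clustering threshold reads as
"roughly half the UMI length in matches".

Clustering is greedy and seed-based: take the first unassigned extraction
as a seed, absorb every unassigned UMI scoring at least the threshold
against it, repeat. This is `O(k n)` alignments for `k` clusters — the
all-vs-all alternative is quadratic and unnecessary, because 50-mer UMIs at
10% error leave a wide score gap between same-molecule and cross-molecule
pairs. Seeds follow input order, making the procedure deterministic.

The threshold is auto-estimated by clustering a sample (default 500 UMIs)
at every candidate threshold and locating the widest plateau of the
cluster-count curve (longest run of consecutive thresholds whose count
changes by under 5%). The chosen threshold is the upper-quartile point of
that plateau rather than its midpoint: every point on the plateau yields
the same cluster count on the sample, but the full data set probes the far
tail of the cross-pair score distribution, and a threshold in the lower
half of the plateau occasionally absorbs an unrelated (often
mis-extracted) UMI into a cluster. False splits, by contrast, only create
small clusters that the `min_reads` filter removes, so erring high inside
the plateau is strictly safer. Two degenerate plateaus are ineligible: a count
of one (everything merged) and a count equal to the sample size (nothing
merged). Without that rule a threshold range lying entirely above the
attainable scores would return a meaningless midpoint instead of the
"no stable threshold" error. The scan also reports self-pair and
cross-pair score distributions as diagnostics.

Two conventions worth noting: clusters below `min_reads` (default 15) are
excluded from consensus as unreliable, and clusters above `max_reads`
(default 100) contribute only their first 100 members to the pileup. All
members remain *assigned*, so the clustering stays a partition — the cap
limits compute, not membership.

## Consensus calling and filters

Reads are oriented using the extraction orientation and aligned to the
reference end-gap-free (overlap alignment), so construct flanks clip for
free. Candidate mutations are any non-reference pileup allele; indels are
left-aligned (VCF-style) so equivalent calls deduplicate, and insertion
support counts only reads carrying an identical inserted sequence at the
same normalised position. Support is carriers over position-overlapping
reads — reads whose alignment does not span a position are excluded from
its denominator, which prevents end-of-read deflation.

The filters mirror the published quality-control rules:

* support must **exceed** 0.6 (a tie at exactly 0.6 fails — "greater than
  60%" is strict);
* when both strands contribute at least 5 overlapping reads, each strand
  must individually show at least 0.3 support, depleting
  direction-consistent errors;
* a result with more than 16 passing mutations is discarded whole, since a
  mean-3.5 Poisson load makes such variants overwhelmingly likely to be
  chimeric or misclustered.

The support-fraction histogram (`plot_support_histogram()`) exposes mixed
clusters (mass near 0.5); they are not auto-removed, only visible, since
there is no principled automatic cutoff that does not also bite true
heterogeneity.

Accuracy evaluation compares the implied consensus (reference plus passed
calls) with the true template by edit distance, so it is independent of the
caller's own bookkeeping.

## Evolutionary analyses

* **Demultiplexing** scores every round barcode against the
  barcode-proximal window of up to 10 member reads per cluster and assigns
  by highest median score when the margin over the runner-up is at least 4
  score points; anything closer stays unassigned rather than guessed.
* **Variant deduplication** collapses identical nucleotide mutation sets;
  amino-acid sets are joint re-translations of affected codons (two
  substitutions in one codon translate once). Frameshifted variants are
  flagged untranslatable, never silently dropped — their counts are real
  even when their protein is not interpretable.
* **Similarity networks** connect variants whose amino-acid mutation sets
  differ by at most `d_max = 2` (the symmetric difference metric). Founder
  detection runs on connected components, which are reproducible; the
  t-SNE embedding (fixed seed 7, perplexity 30, implemented in-package on
  the distance matrix) is for display only and no analysis depends on its
  coordinates.
* **Founder variants** are the intersection of all member mutation sets in
  a component. Members carrying extra shared mutations are grouped by
  mutation sharing and recursed, producing sub-lineages whose labels list
  only the mutations they add.
* **Positional enrichment** restricts to variants persisting into the
  final round and compares count-weighted per-residue mutation frequencies
  between two rounds, with pseudocount `eps = 1/(total qualifying count)`.
  The frequencies are exactly scale-free; the pseudocount shrinks with
  depth, so factors are asymptotically scale-free and always finite. A
  fixed `eps` can be supplied where exact invariance under count rescaling
  matters more than the adaptive default.
* **Epistasis** compares a mutation's effect alone (`act(m)/act(parent)`)
  and inside a background (`act(B+m)/act(B)`), with 95% CIs propagated
  Gaussian-fashion from the activity table. A *sign* call requires the two
  effects to deviate from 1 in opposite directions with both CIs excluding
  1. The directional rule alone is not symmetric in `m` and `B` (one
  mutation can flip sign while its partner's classification reads
  "magnitude"), so the classifier evaluates both directions and reports
  sign if either flips with CI support; the magnitude criterion — the
  interaction ratio `gamma = act(mB)/(act(m) act(B))` outside
  `[1/tau, tau]`, default `tau = 1.5` — is inherently symmetric. This
  makes the pairwise case invariant to which set is labelled "background",
  which is the behaviour a reader of a pairwise interaction table expects.

## Numerical and scale choices

Alignment kernels are compiled (Rcpp): score-only Smith-Waterman for
clustering, and a full-traceback overlap aligner for consensus, with
deterministic tie-breaking and post-hoc indel left-alignment.
Ties in the DP take the leftmost optimal end; determinism across reruns is
asserted in the tests byte-for-byte.

The test-bench runs at desk scale chosen to keep a laptop-class single-CPU
run comfortable while preserving the published operating points: accuracy
analogs use 100 templates x 50-fold coverage and 180 templates x 35-fold
coverage of a 1250-bp gene at 10% read error; generator calibration uses a
100,000-member library; clustering-efficiency grids use hundreds of UMIs
per grid point rather than millions. These sizes are statements about the
statistics being stable at that scale, not about limits of the method.

## Known limitations

* No homopolymer-length-dependent or signal-level error modelling; no
  PCR chimera simulation.
* Quality strings are parsed but unused — the method filters on read
  support, not base quality.
* In-frame codon-aligned indels are flagged untranslatable along with
  frameshifts; the variant record keeps its nucleotide calls either way.
* Demultiplexing assumes barcodes at the construct start; exotic layouts
  need the window parameter adjusted.
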