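---
title: "Methods: cistrome-transcriptome integration on synthetic data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cistrome-transcriptome integration on synthetic data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cistromer` re-implements, as tested and reusable components, the analysis
chain used to characterise a hormone receptor's genome-wide binding
(its *cistrome*) against the transcriptome it regulates: input-controlled
peak calling from aligned sequence tags, response-element and cofactor
motif analysis, peak-to-gene association statistics, cross-cell-line
comparison, and differential-expression integration.  Every stage is
exercised against a synthetic-data generator with planted ground truth, so
each claim the pipeline makes (a peak, a motif, an association, a cluster)
can be scored against what was actually planted.

## The measurement model

ChIP-seq tags are 5' positions of sequenced fragment ends.  A fragment of
length $L$ spanning a binding site contributes one tag at its left end (+
strand) or right end (- strand), so plus- and minus-strand pileups flank
the true site, separated by roughly the mean fragment length.  The *peak
shift* — half that separation — re-centres tags onto the site.  Tags
aligning to $m$ genomic positions (multireads) carry weight $1/m$, capped
at multiplicity 10.

Peak calling follows the documented parameter semantics of the
enriched-region approach used with an input-DNA control:

1. shift tags by the learned (or given) shift, + strand right, - strand
   left;
2. cluster shifted tags into maximal runs with gaps at most `merge_gap`
   (200 bp by default, about the minimum sonication fragment);
3. keep a candidate iff its weighted tag sum, normalised to reads per
   million (RPM) by the ChIP library size, reaches `min_rpm` (10), **and**
   its fold enrichment over the library-size-scaled control count — with
   the denominator floored at one pseudo-tag — reaches `fold_threshold`
   (4);
4. the summit is the position of maximal weighted coverage (leftmost on
   ties); the false discovery rate is estimated by swapping the ChIP and
   control roles and re-calling.

We implement the parameter semantics (shift, four-fold background, 10 RPM,
$1/m$ weighting, swap FDR), not any particular tool's internals, which are
not specified by its published description.  Shift learning estimates, per
candidate pileup, half the distance between the weighted modes of the
minus- and plus-strand tag positions and takes the median over pileups.
Mode estimation on a handful of tags is meaningless, so candidate pileups
must hold at least 8 weighted tags with at least 2 per strand in a 1 kb
window, in addition to the RPM floor.

## Motif analysis

The progesterone response element (PRE) is the palindromic inverted repeat
`RGNACAnnnTGTNCY`.  `pre_pwm()` builds a position probability matrix from
this consensus with degenerate positions split evenly over their IUPAC
sets; the shorter core element is kept as the IUPAC pattern `CWNNNTGTNC`
(the published rendering of the core is ambiguous as a matrix, so it ships
as a pattern).  Matrices in MEME minimal format can be read and written.

Scoring is the standard log-odds sum $\sum_i \log_2 p_i(b_i)/q(b_i)$ with
a 0.001 pseudocount; the match p-value is $P(S \ge s)$ under the
background model, computed by dynamic programming over the score
distribution.  For widths up to 10 the full $4^w$ lattice is evaluated, so
the p-value is exact; for wider matrices the distribution is discretized
on a 0.001-bit grid with floor rounding, which can only understate
significance.  Strength classes follow the published bins: strong
($p < 10^{-5}$), moderate ($10^{-5} \le p \le 10^{-3}$, a closed
interval — the boundary $10^{-5}$ is assigned to moderate because the
strong bin is written with a strict inequality), weak/absent
($p > 10^{-3}$).

Scanning covers both strands of ±400 bp around each summit at the default
report threshold $p < 0.01$.  Note that 0.01 is a *per-window* threshold:
an 800 bp region offers ~1600 windows, so almost every region contains a
reported hit by chance.  Region-level "contains a PRE" calls therefore use
the strong class, where the chance rate is ~1.6% per region while planted
consensus instances always score strong ($p \approx 4\times10^{-6}$).
Overlapping opposite-strand hits at the same window collapse to the lower
p-value (ties to +); the background model for p-values defaults to the
0-order base composition of the scanned sequences.

Enrichment against a matched background uses the cumulative hypergeometric
tail on region counts, with background regions sampled length-matched,
non-overlapping, and GC-matched within 5 percentage points (bounded
retries, then the nearest-GC candidate).  Published GC-correction
weighting schemes are not described in enough detail to replicate, so
plain GC-matched sampling stands in.

## Association statistics

All distances are measured from the region midpoint to the TSS, signed
negative upstream of the gene on its own strand.  Where published
accounting mixes "within 100 kb of a TSS" and "of the gene", we
standardise on the TSS anchor throughout; equidistant genes are broken by
lexicographically smallest identifier for determinism.  Interval overlap
requires at least 1 bp under half-open coordinates, matching default
`intersectBed` behaviour.  The summary report mirrors the canonical
binding-characteristics table: every row is a numerator/denominator pair,
densities are regions-within-100 kb over genes-with-at-least-one-region,
and the rendered table rounds percentages half-up to one decimal (the
densities to two — the printed source rounds one such quotient, 1239/559,
to 2.23 where the true quotient is 2.216; we always print the computed
quotient).

Hypothesis tests are authored in the package with independent oracles in
the test suite: two-sample Kolmogorov-Smirnov (exact lattice-path p-value
for tie-free samples with $n_a n_b \le 10^4$, asymptotic with the standard
small-sample correction otherwise), one-sample KS against a fitted normal
(no Lilliefors correction; this is lenient toward normality and treated as
qualitative), Kruskal-Wallis with tie correction, Welch's t (the published
analyses say only "unpaired t test"; Welch is the robust default), the
cumulative hypergeometric tail in log-gamma arithmetic, Fisher's exact
2x2, and closed-form OLS/Pearson $R^2$.

## Expression integration

A transcript is progestin-regulated when it passes $p < 0.01$ and linear
fold change $\ge 1.5$ at one or more of the 2, 6, 24 h time points, with
direction from the sign at the lowest-p passing time point.  Time-course
profiles are clustered with a seeded online Kohonen SOM (default 3x3 grid
matching the nine published clusters, 2000 presentations, Gaussian
neighbourhood, exponentially decaying learning rate and radius; the
published tool's hyperparameters are unstated, so these are our own
defaults).  Cross-condition regulation deltas partition transcripts into
lost / gained / conserved, and distance analyses of those classes use the
same Welch machinery as peak heights.

## What the generator emulates — and what it does not

The generator plants, per cell line: `n_sites` binding sites of width
300 bp, a configured fraction at coordinates shared between the two lines;
a PRE in 60% of sites at a normal offset (sd 50 bp) about the site centre;
FOXA1/NF1/AP-1 consensus instances at per-line probabilities that mirror a
FOXA1-rich cancer-like line (44/10/11%) and an NF1/AP-1-rich
immortalized-normal-like line (10/23/28%); and a regulated-gene programme
in which 30% of genes respond (up:down mix 85:15 in one line, 47:53 in the
other) from an onset time point onward, with 60% of regulated genes linked
to a site within 100 kb.  Linked distances are exponential with mean 44 kb
for up- and 75 kb for down-regulated genes, truncated at 99 kb — the
scale of the published median separation — giving the distance tests a
true signal to detect.  ChIP fragments are U[200, 400] bp centred on
sites; each contributes one end tag, so the learned shift should be near
150 bp.  Half of ChIP tags are uniform background; input is uniform; 5% of
tags become multireads with multiplicity 2-10.  Expression effect sizes
are stand-ins (the source reports no effect-size distribution): regulated
transcripts get $|FC| \ge 2$ with near-zero p-values, others
$\log_2 FC \sim N(0, 0.15)$ with uniform p-values.

Default geometry is 4 chromosomes of 25 Mb with 300 genes and 20 000 tags
per library.  These are joint choices, not independent ones: the
region-forming semantics merge tags with gaps under 200 bp, so background
tag spacing must sit far above the merge gap (here ~10 kb) or background
chains masquerade as regions; the one-pseudo-tag fold floor means a
four-tag chain over an empty control window passes the fold filter, so
expected background chain counts are kept below one per genome; and the
swap-based FDR needs the same property with the roles reversed, which is
why the input library is not made much denser than the ChIP library.
Recovery of the configured 60% linkage is only observable when unlinked
genes are rarely within 100 kb of a site by chance, hence the sparse gene
and site density.  Tests that need only coordinates (peak recovery, shift,
linkage, overlap) run with `sequence = FALSE`, which skips sequence
generation and motif planting.

Real data differ in ways the generator does not attempt: non-uniform base
composition and repeats (GC bias, mappability), overdispersed background,
fragment-size distributions with tails, bound-region substructure,
microarray normalisation artefacts, and genuinely unknown truth.  Passing
the planted-truth suite shows the machinery is correct and calibrated
under the stated model, not that any biological dataset will reach the
same operating point.

## Numerical choices and degenerate inputs

Sub-seeds per stage are derived deterministically from the master seed, so
partial re-runs reproduce exactly.  Summit and mode ties break leftmost;
equidistant genes break lexicographically; opposite-strand motif ties
break to +.  Zero denominators render as `NA` sentinels rather than
errors; a region on a chromosome without genes gets an `NA` nearest gene;
degenerate variance in t-tests returns p = 1 at equal means; all-tied
Kruskal-Wallis input returns H = 0, p = 1; the FDR of a run with no
forward peaks is `NA`.  The discretized PWM p-value clamps to the smallest
positive tail mass rather than returning 0.

## Problem sizes

The test suite runs the full two-line pipeline on 2 chromosomes x 8 Mb
with 5 000-tag libraries, peak-recovery and overlap checks on the default
4 x 25 Mb geometry without sequence, motif scans on 500 planted 800 bp
regions, and permutation oracles at $10^4$ draws; the acceptance script
runs one full default-geometry pipeline plus the distance, SOM and
positional analyses.  These sizes are the package's own choices for a
reproducible desk-scale study.

## Known limitations

The package does not reproduce any published dataset's absolute counts
(those require the original raw sequencing data); it anchors all
gene-level accounting to TSSs; it has no exon/intron substructure,
alternative TSS handling, or real-genome ingestion; de novo motif
discovery is out of scope (matrices come in, from consensus or MEME
files); and the swap FDR is only the documented estimator, which can
differ from other tools' internal computations.
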