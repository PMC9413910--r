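---
title: "UBCS: model, estimators, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{UBCS: model, estimators, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ubcs)
```

## The statistic

GC-biased gene conversion (BGC) is a recombination-associated repair bias
that favours G:C over A:T at heteroduplex mismatches.  Its fingerprint in
genome comparisons is a local excess of *weak-to-strong* substitutions —
fixed changes from an ancestral A or T to a derived C or G — concentrated
in tight clusters, most visibly near telomeres.  Because the intensity of
this process is roughly stable over the relevant timescales, the amount
of clustered weak-to-strong signal a chromosomal region has accumulated
behaves like a clock: a region that stopped being telomeric (for example,
the internal remnant of an ancestral chromosome-end fusion) stops
accumulating it.

The package quantifies the signal with the UBCS statistic.  Substitutions
between a target and a query genome are polarized with an outgroup base:
if the target equals the outgroup the change happened on the query
lineage, and vice versa; a substitution is *biased* when the outgroup
base is A/T and the derived base is C/G.  A substitution is a *clustered
substitution* (CS) if some 300 bp window contains it together with at
least four others, and a *biased clustered substitution* (BCS) if some
such window additionally holds at least 80% weak-to-strong substitutions
(the flagged substitution itself need not be biased).  For every disjoint
1 Mb region the statistic is

U = observed BCS count − expected BCS count,

where the expectation is taken under a null in which each substitution in
the region carries an independent Bernoulli(p̂) bias label, p̂ being the
region's observed weak-to-strong fraction.  U therefore measures the
*association* between clustering and bias, not either margin alone: a
region can be rich in biased substitutions, or rich in clusters, and
still have U ≈ 0.

## Exact expectation by bin compression

The expected count is the sum over substitutions of the probability that
the substitution is biased clustered, which is the probability of a
*union* of events — one per candidate window containing it.  With window
starts on every coordinate (`start_divisor = 1`) up to 300 windows
overlap one substitution, and their events are strongly dependent.

The computation proceeds in three steps, each exposed as a function:

1. **Representative windows** (`select_representative_windows`).  Among
   the candidate windows containing the focal substitution, windows with
   fewer than 5 substitutions have probability zero and are dropped;
   windows containing the same substitution set define the same event
   and are collapsed to one witness (the smallest start is kept — any
   choice gives the same probability).  The number n of representatives
   is bounded by the number of substitutions in the covering region.
2. **Bin compression** (`compress_to_bins`).  The ordered starts and
   ends of the n representative windows cut the covering region into
   2n−1 *bins*; bin i stores its substitution count.  Cluster k (bins
   k..k+n−1) recovers exactly the content of representative window k,
   and the focal substitution sits in the middle bin.
3. **Telescoping union** (`prob_bcs`).  With A_k the event that cluster
   k holds at least the threshold fraction of biased labels,
   P(∪A_k) = P(A_1) + Σ_k P(A_k ∩ ¬A_1 ∩ … ∩ ¬A_{k−1}).  Each term is
   expanded by the law of total probability over the joint counts of
   biased substitutions in the n−1 bins shared between consecutive
   clusters; given those counts, the past (¬A_1…¬A_{k−1}) and the
   present (A_k) are conditionally independent, so the dynamic program
   carries a single table keyed by the shared-bin counts, updating it by
   one bin per step.  Memory is bounded by Π(b_i+1) ≤ 2^c and time by
   n·2^c, with c the substitution count of the covering region.

The implementation is validated against an independent brute-force
oracle (`brute_force_prob_bcs`) that enumerates all 2^s label
assignments and candidate windows directly; the suite checks agreement
to 1e−9 on hundreds of randomized instances, and the acceptance script's
worked examples pin the closed-form cases (a single 5-substitution
cluster at p = 0.5 has probability 0.1875, the upper binomial tail).

Numerical choices:

* The 80% threshold is compared in exact integer arithmetic
  (`count · den ≥ num · cluster_size`), so 4/5 or 5/6 biased pass
  exactly and no floating-point boundary artefact can flip a window.
* Windows must lie inside the chromosome on both the observed and the
  expected side, so the two counts are computed over the same window
  universe near chromosome ends.
* p̂ is taken from the 1 Mb region containing the focal substitution
  even when its windows straddle a region boundary; clusters are built
  chromosome-wide.
* Covering regions with more than `c_max = 22` substitutions switch to
  a seeded Monte-Carlo estimate (default 1e5 label draws) with a
  warning; 2^c work is infeasible for such hyper-dense knots and they
  are vanishingly rare away from pathological inputs.
* `start_divisor = 150` reproduces the historical coarser scheme of
  windows anchored at multiples of half the window length; probabilities
  under a coarser grid can only be smaller (a union over a subset of
  windows), which the suite checks as a monotonicity property.

## SND calling and polarization

Single-nucleotide differences are read from pairwise alignments (MAF) or
a precomputed three-way TSV (target, query, outgroup per target
position).  An SND is discarded when its 11 bp context window (five
columns each side) contains an indel, more than two target–query
differences (the focal SND counts as one of the two allowed), or when no
outgroup base is available at the SND column.  A window truncated by a
contig edge, or with non-contiguous position coverage, is discarded
conservatively.  Coordinates are 0-based half-open on the target genome;
soft-masked lowercase bases are uppercased before comparison; ambiguity
codes disqualify the SND column but count as differences in the context
only when both bases are plain A/C/G/T and differ.  Liftover to the
outgroup is deliberately externalized: the pipeline consumes the
three-way TSV, and `add_outgroup()` joins an outgroup track onto MAF
columns by target coordinate.

## Divergence proportions between species

For two catalogs sharing the human reference coordinates, the ratio of
summed UBCS over the M = 10 telomeric 1 Mb windows of a chromosome arm
estimates the ratio of accumulation times of the two query lineages,
because BCS counts grow linearly with time under a stable process.  The
distance is the median ratio over 28 control telomeres (10 p-arms, 18
q-arms; acrocentric short arms and rearranged arms are excluded), and
the confidence interval is a bootstrap that resamples 15 of the 28
telomeres and 8 of the 10 window offsets with replacement (one window
draw shared across the telomeres of a replicate; a per-telomere variant
is available behind a flag), 1000 replicates, trimming 2.5% from each
tail.  "Eliminating 5% of the most extreme values" is read as a central
95% interval; the one-sided alternative would not be an interval.
Telomeres whose denominator sum is not positive are excluded with a
warning — UBCS can legitimately be negative, and a non-positive
denominator makes the ratio meaningless rather than merely noisy.
Multiplying the proportion by the fixed 6 Mya human–chimpanzee split
converts it to a speciation time; the interval rescales linearly.

## Fusion-time estimation

R is the fraction of the 6 Mya since the human–chimpanzee split during
which the two ancestral chromosomes were *not* fused, so the fusion time
is 6 Mya · (1 − R), clamped to [0, 6].  R is approximated as q1/q2:

* q1 compares human-derived to query-derived UBCS summed over the two
  L-length intervals flanking the fusion site (L swept over 15–20 Mb;
  one-sided variants are available since the homology of each flank to
  the chimpanzee 2A/2B p-arms is not resolvable in human coordinates).
* q2 is the median, over both arms of control chromosomes 1–12, 16, 17,
  of the ratio of human-derived UBCS in the first L bp of a telomere to
  the same length starting 5 Mb in.  It calibrates how much telomeric
  signal the query-derived measurement near the site misses because the
  outermost chimpanzee sequence (repeat-capped) is not alignable to the
  human reference.

The point estimate uses the median of R(L) over the L sweep.  For the
interval, each bootstrap replicate draws one L uniformly, resamples the
1 Mb regions of the fusion flanks with replacement — jointly for the
two profiles, preserving their pairing by location — to recompute q1,
and resamples the control telomeres with replacement to recompute q2;
the replicate times are trimmed 2.5% per tail.  Resampling only
telomeres and L would treat q1 as noise-free and demonstrably
undercovers: the flank regions carry the dominant sampling noise of the
whole estimator, and the paired block bootstrap over regions restores
it.  Replicates with R > 1 clamp to a time of 0, as the point estimate
does.

## What the synthetic generator emulates

`simulate_catalog()` draws a Neyman–Scott process: background
substitutions from a homogeneous Poisson process; cluster centres from
an inhomogeneous Poisson process whose intensity is an interior constant
plus an exponentially decaying telomeric term at each chromosome end
(and optionally at an internal "fusion site"); Poisson(6) members per
centre scattered uniformly over 250 bp and reflected at chromosome ends;
bias labels Bernoulli(p1 = 0.92) inside clusters and Bernoulli(p0 = 0.3)
outside.  All intensities scale linearly with divergence time, which is
the linearity the distance estimator relies on.  A 12 bp minimal spacing
is enforced by rejection, emulating the post-filter catalogs in which no
11 bp window retains more than two differences; positions keep a 5 bp
margin from chromosome ends so alignment fixtures round-trip through the
SND filters.

Two scenario wrappers define the study conditions:

* `simulate_species_pair(t_x, t_y)`: 22 autosomes of 21 Mb (ten 1 Mb
  windows per arm plus a one-region buffer), background 40 subs/Mb/Mya,
  telomeric amplitude 4 centres/Mb/Mya decaying over 3 Mb.  The true
  proportion is t_y/t_x by construction.
* `simulate_fusion_scenario(split, fusion)`: control chromosomes
  1–12, 16, 17 of 55 Mb (each arm accommodates the 5 Mb offset plus the
  20 Mb maximal probe) and a 100 Mb fused chromosome with the site at
  50 Mb, far enough from its own telomeres that their 6 Mb decay does
  not contaminate the flanks.  The site accumulates human-derived
  signal only for split − fusion Mya; the query-derived site source
  runs the full period but with amplitude damped by e^(−offset/decay),
  which for an exponential profile is exactly the outward shift by the
  5 Mb rescaling offset — the cap effect q2 exists to correct.  With
  that construction q1 = R · q2 holds identically in the linear regime,
  so the estimator is consistent on its own assumptions.

The fusion scenario uses a deliberately heavy background (300
subs/Mb/Mya against a telomeric amplitude of 12 centres/Mb/Mya).  The
reason is a real property of the statistic worth knowing about: U per
cluster shrinks as the region's p̂ rises, because the expected count is
a steep function of p̂.  If cluster members dominate the local
substitution pool, p̂ climbs toward p1 near telomere starts and the
first megabases yield less U per cluster than the interior — a gradient
that deflates the rescaling factor q2 and biases the recovered fusion
time downward.  Keeping the per-region weak-to-strong fraction in the
0.3–0.45 band, as on real chromosomes, keeps that nonlinearity small;
it does not remove it, which is one reason the recovery tolerance is
0.3 Mya rather than zero.

What the generator does *not* emulate: nucleotide-level context (no
CpG hypermutability, no rate heterogeneity beyond the cluster process),
alignment error, assembly gaps, segmental duplications, and the
asymmetric alignability around the real fusion site.  Passing the
recovery tests therefore demonstrates that the estimators are correct
and calibrated on their stated assumptions — not that those assumptions
hold on any particular genome pair.

## Problem sizes in the test suite

The suite exercises the exact algorithm against brute force on covering
regions of up to 12 substitutions (where 2^s enumeration is affordable),
null-calibrates the statistic over 500 label redraws on a fixed 2 Mb
clustered layout, and runs 50 independent recovery repeats of each
scenario (about 130 thousand substitutions per catalog for the species
pair, about 1.6 million for the fusion scenario).  These sizes were
chosen so the whole suite completes in a few minutes on one CPU while
leaving the Monte-Carlo error of each check well below the tolerance it
asserts.

## Known limitations

* The Monte-Carlo fallback makes profiles of hyper-dense regions
  reproducible only under a fixed RNG seed.
* Distances are ratios of telomeric sums; when a lineage's telomeric
  UBCS is weak (short divergence times, small M) single telomeres can
  have non-positive denominators and fall out of the median, widening
  the interval.
* The fusion estimator inherits the mild p̂-nonlinearity described
  above; on data with extreme telomeric bias fractions it will
  systematically shade the fusion time.
* The MAF reader expects exactly one target and one query sequence per
  block and blocks that are non-overlapping and ordered on the target.
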