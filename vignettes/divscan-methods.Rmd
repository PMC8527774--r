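---
title: "Methods: hotspot scans and MK tests in divscan"
author: "divscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hotspot scans and MK tests in divscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divscan)
```

# The problem

When two closely related species (for example *Drosophila melanogaster*
and *D. simulans*) are compared across a gene region, substitutions are
rarely spread evenly: regulatory regions in particular can accumulate
changes in short, dense stretches. `divscan` answers two questions about
such a region:

1. **Where along the alignment are substitutions clustered more than a
   uniform process would allow?** (the hotspot scan)
2. **Is the pattern of within-species polymorphism versus between-species
   divergence compatible with neutral evolution?** (McDonald–Kreitman
   style contingency tests, for coding and noncoding regions)

# The cumulative G statistic

Let an alignment have `L` columns and let `x_1 < x_2 < … < x_n` be the
columns carrying interspecies substitution events. The cumulative
deviation statistic at the i-th event is

\[ G_i = \frac{i}{n} - \frac{x_i}{L}, \qquad G_0 = 0 , \]

the difference between the event's relative occurrence rank and its
relative position in the alignment. Under a uniform scatter of events the
profile stays near zero (exactly zero for perfectly even spacing
`x_i = iL/n`); a run of closely spaced events makes G rise. The hotspot
statistic is the maximal rise

\[ \Delta G = \max_{0 \le i < j \le n} (G_j - G_i), \]

and the spanned segment `(x_i, x_j]` (reported 1-based closed as
`[x_i + 1, x_j]`) is the candidate hotspot. We take the maximum over
*all* ordered index pairs, not only consecutive events; the alternative
(consecutive-only) reading of "differences of G between events" is
strictly weaker and is not implemented. Since `G_0 = 0` and
`G_n = 1 - x_n/L ≥ 0`, the statistic is always non-negative.

Only density *increases* are scanned: the method looks for hotspots, not
coldspots.

## Monte Carlo null and exact enumeration

Significance comes from the resampling null: each replicate draws `n`
distinct positions uniformly without replacement from the `L` columns of
the position universe, and computes ΔG exactly as the observed pipeline
does. The p-value uses the add-one estimator

\[ p = \frac{1 + \#\{\Delta G^{sim} \ge \Delta G^{obs}\}}{N + 1}, \]

which never returns zero and makes the Monte Carlo test exact when
`α(N+1)` is an integer; ties count as exceedances. The default is
`N = 100000` replicates. A single seeded generator drives all replicates
in replicate-major order, so a fixed seed gives bit-identical results
regardless of internal vectorisation. The inner loop is implemented in
C++ (Rcpp) but draws from R's RNG, so `set.seed()` governs it.

When the arrangement space is small (`choose(L, n) ≤ 200000` by default)
the p-value is computed by exhaustive enumeration instead and flagged
`"exact"` in the output: small inputs deserve exact answers, and the
threshold keeps enumeration at desktop scale.

## Recursive segmentation into multiple hotspots

`call_hotspots()` tests the whole region; if `p ≤ α` the maximal segment
is reported and the two flanks are re-scanned independently, each with a
fresh null of its own event count and length (the right flank re-based to
start at column 1). Recursion stops when a region is non-significant,
holds fewer than `min_events` events (default 3), or is shorter than
`min_segment_length` columns (default 10). This yields disjoint
significant stretches, naturally accommodating several hotspots in one
region. No multiple-testing correction is applied across recursion
levels by default: each flank test conditions on the parent being
significant, and the type I error of the procedure is controlled at the
top level (verified by simulation, below).

## Position universe

By default the null resamples from *all* `1..L` alignment columns,
following the literal reading of positions "along the alignment". With
`position_universe = "mutually_ungapped"` the event positions are
re-ranked onto the columns where both sequences are non-gap and the null
resamples from those; reported segments are mapped back to alignment
columns. Use this when long indels would otherwise create spurious
event-free gaps.

## Indels

A maximal run of gap columns present in exactly one of the two sequences
is recorded as one indel event anchored at its first column. By default
indels are *not* counted as events in the scan (`include_indels =
FALSE`): whether an indel should count as a single substitution-like
event is a modelling choice, so both behaviours are exposed and the
conservative one is the default. Columns gapped in both sequences
contribute no events but remain part of `L`, which is fixed by the
alignment file.

# McDonald–Kreitman tests

## Pathway counting

For two sense codons differing at `k ≤ 3` positions,
`classify_codon_change()` enumerates all `k!` single-step mutational
pathways, discards pathways passing through a stop codon (keeping all if
every pathway does), labels each step synonymous or nonsynonymous under
the standard nuclear code, and averages over the retained pathways — the
Nei–Gojobori pathway convention. Counts may therefore be fractional;
`syn + nonsyn = k` always. The test suite checks the implementation
against an independent brute-force enumerator over all 61 × 61
sense-codon pairs.

## Counting polymorphism and divergence

`count_mk()` walks codon columns of an aligned ingroup panel (m ≥ 2
strains) plus one outgroup sequence:

* ingroup sequences with a gap or ambiguity in the codon are dropped for
  that codon; alleles at frequency ≤ `maf_threshold` are then excluded
  (default 0, i.e. every observed allele counts; `0.01` reproduces a
  "rare below 1%" filter);
* ≥ 2 surviving alleles → **polymorphic**: each minor allele is
  classified against the ingroup consensus (most frequent allele, ties
  broken alphabetically for determinism);
* a monomorphic ingroup differing from the outgroup → **fixed
  difference**, classified against the outgroup codon;
* a codon both polymorphic and divergent counts as polymorphic only —
  standard MK bookkeeping, where divergence requires ingroup
  monomorphism;
* codons with gaps/ambiguity in the outgroup, stop-codon alleles, or no
  surviving allele are skipped with a warning.

`mk_significance()` tests the resulting 2×2 table. The default is the
Pearson chi-square *without* continuity correction on 1 df (fractional
pathway-averaged counts permitted); a likelihood-ratio G-test and
Fisher's exact test (on rounded counts, with a warning when rounding
changes the table) are options. A zero marginal raises an error
directing the user to Fisher's test.

## The noncoding variant

`count_region_mk()` contrasts **upstream noncoding** changes with
**silent** changes, where silent = synonymous coding changes plus all
intron changes. The annotation is a table of non-overlapping labelled
intervals (`upstream`, `intron`, `cds`) on alignment columns;
concatenated `cds` intervals are read in frame through the codon
machinery above, while `upstream` and `intron` columns are counted
site-wise with the same fixed-vs-polymorphic rules. Columns outside any
labelled interval are simply not counted, so the annotation fully
defines the counting universe.

# The synthetic-data generator

The generator produces the two input shapes the analysis assumes, with
exact ground truth:

* `simulate_pair()` builds a random ancestral sequence and a derived
  copy: background substitutions drawn uniformly without replacement
  outside the windows, each window receiving exactly its planted event
  count at distinct columns, and indel runs placed as gap columns in the
  derived sequence. Strata never collide, so the planted event count is
  exact — which the power calculations below rely on.
* `simulate_mk_panel()` plants each polymorphism or fixed difference in
  a *distinct* codon, using code-verified synonymous or nonsynonymous
  single-base changes between sense codons; polymorphic sites place the
  derived codon in a strain subset at the requested frequency (clamped
  so sites stay polymorphic). One event per codon means no pathway
  averaging, so `count_mk()` recovers the planted table exactly;
  multi-hit codons are exercised separately through the classifier's
  oracle tests.

What the generator does **not** emulate: phylogenetic correlation,
demography and linkage in the polymorphism panel, context-dependent
mutation, rate heterogeneity along the sequence, and alignment error.
Passing tests therefore demonstrate correctness of the statistics under
their own assumptions, not robustness to real-data artefacts.

# Numerical and design choices

* **Coordinates.** 1-based alignment columns internally; BED output is
  0-based half-open. A coordinate map anchors a reference sequence at an
  arbitrary offset (e.g. a negative TSS-relative anchor) so hotspots can
  be reported in promoter coordinates; insertion columns map to the
  preceding reference offset, leading insertions to `NA`.
* **Tie-breaks.** The arg-max ΔG pair is the smallest `i`, then the
  smallest `j`; Monte Carlo ties count as exceedances with a `1e-12`
  tolerance guarding float comparison of identical formulas.
* **Replicate counts.** The single-fixture exact-vs-Monte-Carlo
  comparison uses the default 100,000 replicates. The replicated
  calibration experiments (1,000 null scans for type I error; 200
  planted-window replicates for power; 1,000 neutral MK panels) use
  1,999 replicates per scan: `0.05 × (1999 + 1) = 100` is an integer, so
  the add-one Monte Carlo test has exact size at α = 0.05, and the
  p-value resolution (5 × 10⁻⁴) is far finer than the decision
  threshold. Problem sizes for these experiments: null scans at
  `L = 1000, n = 50`; power at `L = 2000` with 30 background plus 30
  window events in columns 901–1000; neutral MK panels of 90 codons × 8
  strains with 80 events drawn multinomially with independent fate
  (fixed/polymorphic) and type (synonymous/nonsynonymous) margins.
* **Neutral MK calibration.** Planting a fixed equal-ratio table would
  give χ² ≈ 0 in every replicate; calibration requires sampling
  variation, so the planted counts themselves are drawn multinomially
  under independence and the full pipeline (panel simulation → counting
  → test) is run per replicate.
* **Degenerate inputs.** No events → empty call list (not an error);
  `n = L` → every replicate ties the observed arrangement, `p = 1`;
  observed ΔG = 0 → `p = 1`; all-gap reference → error; zero MK table →
  error.
* **Known spec-level ambiguity.** The verbal definition of G leaves the
  normalisation open; the direct formalisation above
  (`G_i = i/n − x_i/L`) is pinned, and ΔG is maximised over all pairs
  rather than consecutive events. Whether indels counted as events in
  the original analyses is likewise unstated; the flag defaults to the
  conservative reading.

# Limitations

* Pairwise scans only; no simultaneous multi-species scan.
* No coldspot (density-decrease) detection and no analytical
  (Kolmogorov–Smirnov-type) p-values.
* Unpolarised MK only (no second outgroup), no asymptotic-α estimation,
  no ML dN/dS.
* Real promoter analyses depend on the polymorphism freeze and the
  aligner used upstream; `divscan` consumes alignments and never
  produces them.
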