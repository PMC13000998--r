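---
title: "Methods: windowed selection statistics, internode rates, editing calls and codon usage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed selection statistics, internode rates, editing calls and codon usage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morffotools)
```

This vignette documents the models and procedures behind each stage of the
pipeline, the parameters that matter, the numerical conventions, and what
the simulator does and does not emulate. It is the design record for the
package: everything here is a statement about how the code works, not an
empirical claim beyond what the test suite itself computes.

## Windowed divergence and dN/dS

The substrate is a codon-aware alignment: frame anchored at column 1, all
rows equal length, alphabet `A/C/G/T/N/-`. Before any dN/dS arithmetic,
`remove_stop_codons()` deletes every in-frame codon triplet in which *any*
taxon carries a stop; deleting whole triplets for all taxa keeps the
matrix rectangular and in frame, and the removed codon indices are
returned so coordinates can be mapped back.

Windows are `window = 90` nt advanced by `step = 3` nt. Both must be
multiples of 3 so every window starts on a codon boundary; a non-multiple
step is rejected rather than silently re-framed, because a frame-shifted
window would scramble the by-codon-position statistics. The window count
is exactly `floor((L - window)/step) + 1`.

**Nucleotide diversity.** Within a window, for codon position *k*, each
unordered taxon pair contributes its proportion of differing sites among
the position-*k* sites where both bases are plain nucleotides; `pi_k` is
the mean of these proportions over pairs. A pair-site with a gap or `N`
counts toward neither numerator nor denominator (missing-data exclusion —
treating gaps as differences would conflate indel history with
substitution). A pair with zero comparable sites is dropped from the mean
and the window flagged.

**dN/dS by counting.** The pairwise estimator is Nei–Gojobori (1986)
counting. Per codon, each of the nine single-nucleotide neighbours is
classified synonymous or nonsynonymous against the standard code; a
change that would create a stop codon is excluded from *both* site
counts, so S + N for a codon is 3 minus a third of its stop-reachable
changes. Site counts for a pair average the two codons. Differences for
codons differing at 2–3 positions average over all orderings of the
minimal mutation paths, with paths through stop intermediates excluded at
equal weight among survivors; in the rare case where every ordering
crosses a stop (possible only between particular sense codons), the
average falls back to all orderings and the pair is flagged `stop_path`.
Raw proportions `pS = Sd/S`, `pN = Nd/N` receive the Jukes–Cantor
correction `d = -(3/4) ln(1 - 4p/3)` when `p < 0.75`; at or beyond that
domain boundary the raw proportion is reported and the pair flagged
`out_of_domain`.

Per window, `dN` and `dS` are means over pairs of the corrected
distances, and `dnds_mean = mean(dN)/mean(dS)`. Pairs that are degenerate
in a window — no comparable codons, `S = 0`, `N = 0`, or out of the JC
domain — are excluded from both means and the window flagged
(`degenerate_pairs`, `no_pairs`, `ds_zero`); windows are always emitted,
flagged rather than dropped, so row indices stay aligned with
coordinates.

The 95% interval is a nonparametric bootstrap over the window's codon
columns (percentile method, seeded; `n_boot = 1000` by default, `0`
disables). The resampling unit is the codon column, not the nucleotide,
to preserve within-codon dependence among the three positions. Internally
all per-pair, per-codon NG86 quantities are precomputed as lookup-table
arrays, so windows and bootstrap replicates reduce to cumulative-sum and
matrix-product arithmetic; this is what keeps a 200-replicate bootstrap
over an 871-window scan in the seconds range.

A deliberate substitution: the windowed dN/dS here is a *pairwise
counting* estimator, not a phylogenetic MG94 likelihood fit. Counting is
exactly specifiable and oracle-checkable (the test suite carries a
brute-force neighbour-enumeration oracle), at the price of ignoring the
tree; for window-scale scans of closely related sequences the two agree
in the regimes that matter (purifying vs neutral vs elevated), and the
output metadata records the estimator. One known property of the
counting method surfaced in testing and is worth stating: between two
codons that differ at multiple positions, path averaging can assign
fractional nonsynonymous differences even when the generating history
was purely synonymous, so "`omega = 0` implies `Nd = 0`" holds only
codon-wise for single-hit codons.

## Internode substitution rates

For a single-gene phylogram, every internal node (the root included) with
at least two descendant leaves defines an internode, identified by its
sorted descendant leaf set. The estimator sums, within the internode's
subtree, each tip's path length to the subtree root and divides by the
corresponding sum from the reference plastome phylogram (relative rate)
or chronogram (absolute rate, substitutions·site⁻¹·Myr⁻¹).

Conventions, each of which the tests pin down:

* **Reference restriction.** Both references are pruned to the gene
  tree's taxon set before any comparison, making "corresponding sums"
  well defined when genes differ in taxon coverage.
* **Monophyly filter.** An internode is used only if its leaf set is
  monophyletic in *both* restricted references; otherwise the row is
  emitted with `included = FALSE` and reason
  `not_monophyletic_in_reference`. This guarantees numerator and
  denominator subtrees share the same most recent common ancestor.
* **Stem exclusion.** The subtree root's own stem branch is not part of
  any tip-to-root path — paths start at the internode. (Whether the
  original procedure included the stem is not determinable from its
  description; excluding it is the reading consistent with "tip-to-root
  distances" and is applied to numerator and denominator alike, so a
  shared stem would cancel only approximately, not exactly.)
* **Pseudogene exclusion.** With `exclude_pseudogenes = TRUE`, tips whose
  frameshift count is positive are pruned before enumeration — the
  conservative variant that keeps only sequences presumed under
  functional constraint. Flags naming taxa absent from the gene tree are
  a hard error rather than a silent no-op.
* **Label harmonisation.** Exact string match after trimming and
  whitespace-to-underscore normalisation; an unmatched gene-tree taxon is
  a hard error, never a silent drop.
* **Rooting.** Gene trees are used exactly as rooted; no re-rooting is
  attempted, so rooting fidelity is the caller's responsibility.

Per-gene summaries use type-7 (linear-interpolation) quartiles — R's
default and the most common convention — with Tukey whiskers at the most
extreme values within 1.5 × IQR and points beyond listed as outliers. A
relative fence tolerance of `1e-8·(|q1|+|q3|+1)` prevents floating-point
ties from being classified as outliers when the IQR is zero. Summaries
default to pooling all included internodes of a gene; because the
aggregation level of per-gene boxplot points is a genuinely open choice,
the per-internode rows are always emitted so callers can re-aggregate.

Two exact identities anchor the estimator: a gene tree identical to the
reference phylogram yields relative rate 1 at every internode, and
scaling all gene branches by *c* scales every estimate by *c*.

## RNA-editing classification

The caller consumes per-site base-count tables (reference base, total
mapped reads, counts of each nucleotide) assumed already oriented to the
CDS sense strand. The candidate edit base at a site is the non-reference
base with the highest count; a tie produces one candidate row per tied
base, none auto-passed, since ambiguous sites warrant review rather than
an arbitrary pick. A candidate passes when `coverage >= 10`,
`edit_reads >= 3` and `edit_reads/coverage >= 0.10` — all three
inclusive, the boundary reading consistent with the "≥" form of the other
thresholds. Efficiency is reported for every candidate so near-threshold
sites remain visible. Only C-to-U and U-to-C candidates count toward
summaries by default ("other" mismatches are retained, flagged); the
summary reports genes-with-editing, their fraction, passed sites, and
passed sites over total surveyed bases. Effect annotation places the site
in its codon (`codon_pos = ((offset-1) mod 3) + 1`), applies the edit,
and translates both codons; offsets outside the CDS (the ±100 nt flanks)
are `noncoding`.

## RSCU and ordination

Codon counting skips codons containing `N` or gaps and drops a terminal
stop. RSCU for codon *j* of family *i* (n_i synonymous codons, family
total X_i) is `x_ij / (X_i / n_i)`; families with `X_i = 0` yield `NA`.
Met and Trp are excluded (single-codon families carry no usage signal),
as are stops, leaving 59 codons. Gene filtering keeps CDSs *strictly
longer* than 500 nt by default — deliberately distinct from the ≥ 500 nt
ORF-scanner threshold, with `strict_gt = FALSE` to relax.

PCA runs on the centered, *unscaled* RSCU matrix: RSCU is already
dimensionless and family-normalised, so unit-variance scaling would
inflate rare-family noise (a `scale.` switch exposes the alternative).
Unobserved-family `NA`s are imputed as 1 — the no-information expectation
under uniform usage — rather than 0, which would fake extreme bias;
imputed genes are flagged. Sign indeterminacy of the SVD is fixed by
requiring the largest-magnitude loading of each component to be positive,
making scores reproducible across runs and row orders.

## ORF scanning

Six frames (three forward, three on the reverse complement), ATG starts
only, stops TAA/TAG/TGA, length counted *including* the stop codon with a
500 nt default minimum — the convention of the interactive ORF finders
used to nominate mobile-ORF candidates; both choices are explicit
arguments because tools differ. Per stop per frame only the longest ORF
(first in-frame ATG after the previous stop) is reported, avoiding nested
duplicates. A codon containing `N` can neither start nor stop an ORF but
may be spanned by one — conservative toward detection. Coordinates are
0-based half-open internally and 1-based inclusive in user-facing TSVs.

## The simulator: what it emulates, and what it does not

`sim_config()` defaults describe the study system the analyses assume: a
crown age of 136 Myr (the younger fossil calibration bound; the 231.11
Myr maximum is carried as metadata), a base rate of 2.5 × 10⁻⁴
substitutions·site⁻¹·Myr⁻¹ — the order of magnitude of plastid coding
DNA, giving canonical tip-to-root phylogram depths near 0.034
substitutions/site — purifying selection at ω = 0.2, transition bias
κ = 2, mean read coverage 100 and per-base error 0.01.

Trees come from a seeded pure-birth process rescaled to the crown age
(hence exactly ultrametric); the phylogram multiplies branches by the
base rate, with optional lognormal per-branch noise (mean-preserving,
`branch_sigma`, default 0 = strict clock). The codon model is
MG94-flavoured: single-nucleotide steps only, target-codon-frequency
weighted, κ on transitions, ω on nonsynonymous changes, zero rate to
stops; the generator matrix is scaled to one expected substitution per
site per unit branch length and exponentiated via the reversible
eigendecomposition. Gene panels emit *branch-length-true* gene trees
(chronogram × base rate × class multiplier) alongside alignments, so the
rates module is testable in isolation from tree-inference error — tree
inference itself is out of scope. Pileups draw coverage from a Poisson
(so the coverage threshold is exercised stochastically), edited reads
from a Binomial at the planted efficiency, and errors uniformly over the
three non-reference bases. Codon-usage classes are i.i.d. codon draws
from class frequency vectors; `example_codon_freqs()` provides
AT3-biased, GC3-biased and uniform vectors.

What the simulator does **not** reproduce — and therefore what passing
tests do not establish about real data: indels and alignment error
(alignments are generated gap-free; the gap-handling paths are exercised
by constructed fixtures instead), among-site rate heterogeneity,
selection variation along a gene (the flat-ω model cannot create the
elevated-dN/dS subregions that betray an intergenic spacer inside a
merged alignment), tree-inference error in gene phylograms,
reference-mapping artifacts such as paralog cross-mapping in pileups, and
real codon-usage covariance structure (i.i.d. draws have no
within-family correlations). Recovery results on simulated data bound
the estimators' correctness, not the field behaviour of the full
laboratory pipeline.

## Problem sizes and determinism

The test suite and the acceptance script run everything at desk scale,
chosen as the smallest sizes at which each statistical property is
comfortably non-marginal: 10 taxa × 900 codons with a 200-replicate
bootstrap for the windowed scan; 12 taxa, 20 + 5 genes × 100 codons for
the rate contrast; 1000-codon alignments for ω recovery; 12–15 genes per
class × 250 codons for the ordination checks. Every stochastic path is
seeded — simulation seeds derive from the master seed, bootstrap seeds
are explicit arguments — and generator outputs are byte-identical under a
fixed seed, which the suite asserts.

## Known limitations

Pairwise counting dN/dS saturates sooner than likelihood estimators (the
JC domain ends at p = 0.75) and ignores shared ancestry; bootstrap
intervals are percentile intervals, which undercover slightly in skewed
small-window regimes; the rates estimator inherits whatever error the
input gene trees carry, and with real (non-branch-length-true) trees the
monophyly filter trades internodes for comparability; the editing caller
implements thresholds only — the manual curation a careful study layers
on top (low-coverage regions, paralog cross-mapping) is procedural, not
algorithmic, and stays with the analyst.
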