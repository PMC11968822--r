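---
title: "Methods: comparative CRISPR dropout screen analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative CRISPR dropout screen analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprselect)
```

## The problem and the model

Pooled knockout screens infect a cell population with a genome-wide guide
library at low multiplicity, so each cell carries (mostly) one guide, and
let the population grow for a fixed number of doublings. Guides knocking
out genes required for proliferation become underrepresented between the
post-selection baseline (T0) and the endpoint (here 14 population
doublings, T14). Run in parallel across several cancer lines and one
nonmalignant line, the *difference* in depletion exposes cancer-selective
dependencies — the therapeutically interesting class.

The analysis chain is:

1. **Quantification.** Each amplicon read carries the guide spacer
   immediately after the fixed vector barcode `GAAACACCG`; we take the 20
   bases following the barcode's first exact occurrence and match them
   exactly against the library. Mixed-length stagger prefixes are handled
   by searching rather than by fixed offset. No mismatch tolerance: with a
   9-nt barcode and an exact 20-mer lookup, sequencing errors lose a read
   (tallied as unmatched) rather than misassign it, which at screen depths
   is the cheaper error. Reads are not reverse-complemented (fixed amplicon
   orientation is assumed) — a documented limitation.
2. **Normalization.** Median-of-ratios size factors over guides detected in
   all samples; this reference set excludes dropouts, so depth estimates
   are not dragged down by true depletion. When undefined (single sample,
   or no guide everywhere nonzero) the pipeline falls back to total-count
   scaling and says so.
3. **Fold change and z-score.** Per line,
   `LFC = log2((T14 + 1)/(T0 + 1))` on the normalized scale with
   replicates averaged before the ratio; then `z = (LFC − mean)/sd`
   (n−1 denominator) over *all* guides of that line, targeting and
   control alike. Standardizing per screen is what makes scores comparable
   across lines of different overall screen strength, and including
   controls keeps the reference frame anchored to the full library rather
   than to a shifting targeted subset.
4. **Gene scores.** Gene score = median guide LFC; CRISPR viability score
   = median guide z. Medians of even sets take the midpoint mean. Controls
   aggregate under the `NO_TARGET` pseudo-gene, which gives scoring and QC
   a neutral yardstick but is excluded from calls.
5. **Hit calling.** Per-line negative cutoffs on the gene score (−1
   default; −0.5 for a line whose screen separates reference sets less
   well), a minimum of 2 guides at/below the cutoff, and the constraint
   that the nonmalignant line's response is not more pronounced than any
   cancer line's.

## Call precedence

"Exactly one call per gene" needs an ordering, because a pan-essential
gene can satisfy both the common-depletion rule and — whenever the normal
line's z happens to be the least negative of the four — the selective
rule. We therefore check `common_depleted` **first**: any gene passing
cutoff and guide support in the nonmalignant line too is a common
essential, never cancer-selective. This is also the only ordering
consistent with the monotonicity we assert in tests (deepening the normal
line can only move a call toward common/none) and, empirically, the one
under which planted core essentials never leak into the selective list.
The selective rule then requires depletion in every cancer line plus the
normal constraint; `enriched` uses mirrored positive cutoffs (the
enrichment direction has no published threshold, so symmetry is the
neutral choice); everything else is `none`.

Two readings of the normal constraint are exposed: `gene_level` (default)
compares viability scores — the cross-line comparable unit — and
`guide_level` demands each scoring guide be less depleted in the normal
line than in the cancer line where it scores, the stricter per-gRNA
reading. The ≥2-guide rule is enforced per cancer line by default
(`scoring_guides_scope = "pooled"` relaxes it), and each line's own cutoff
also defines what "scoring" means there.

## Screen QC

- **Gini index** of per-guide counts (zeros included — representation skew
  is a property of raw coverage), computed from the sorted-counts form and
  equal to the mean absolute pairwise difference over twice the mean.
- **Essential-gene depletion**: one-sided Wilcoxon rank-sum of
  essential-gene guide LFCs vs non-targeting controls. Rank-based because
  LFC distributions are heavy-tailed; the choice of test statistic here is
  this package's, and its null calibration is itself tested (p-values
  uniform over 200 null screens).
- **ROC-AUC**: essential genes as positives, nonessential as negatives, a
  gene called positive when its score ≤ threshold, thresholds swept over
  observed scores with ties sharing a threshold, trapezoidal area. This
  construction provably equals the Mann–Whitney c-statistic with half
  credit for ties; the equivalence is asserted against exhaustive pair
  counting, and against pROC, in the tests. ROC uses the gene score by
  default (a flag switches to the viability score).

## The generative model

`simulate_screen()` draws, per guide $i$ in line $l$:

$$p_i^{T0} \propto \mathrm{Lognormal}(0, \sigma^2), \qquad
  p_{il}^{T14} \propto p_i^{T0} \cdot 2^{\,d f_{g(i)l} e_i}, \qquad
  c_{ilr} \sim \mathrm{NB}(\mu = D\,p,\ \text{size} = 1/\phi)$$

with $d = 14$ doublings, fitness $f$ the per-doubling log2 growth deficit
of the guide's gene in that line, efficacy $e_i \sim \mathrm{Beta}(9, 1)$
(mostly-active guides; controls 0), depth $D$ = 500 reads per guide, T0
skew $\sigma = 0.5$, and dispersion $\phi = 0.05$ (Poisson at 0).
Endpoint abundances renormalize to 1 per sample, so neutral genes share a
small positive offset — exactly what median-of-ratios normalization
absorbs. Defaults mirror the study design: 1,000 genes × 4 guides + 50
controls, 1 nonmalignant + 3 cancer lines, triplicates, classes 10%
core-essential / 5% cancer-selective / 2% enriched with $f = -1$
(depletion) and $+0.3$ (enrichment). Where the emulated screen's
count-level noise was not published, $\sigma$, $\phi$ and the efficacy
shape were fixed once at values typical of amplified genome-wide libraries
and production screens, and are not tuned thereafter.

What the generator deliberately does **not** model: infection multiplicity
and selection bottlenecks (absorbed into $\phi$), per-guide dispersion,
copy-number cutting toxicity, off-targets, clonal Cas9 heterogeneity, and
read-level sequencing errors (FASTQ emission is exact). Passing recovery
tests therefore demonstrates the pipeline's correctness and the design's
statistical adequacy under these idealized conditions — not robustness to
every artifact of real screens.

`simulate_fastq()` realizes a count column as reads (random stagger prefix
cycled over lengths 0–7, barcode, spacer, fixed scaffold suffix); prefixes
are re-drawn in the rare case they would create an earlier barcode
occurrence, making quantify-after-emit exactly the identity.

## Numerical and interface choices

- Pseudocount 1.0 on the normalized scale bounds the LFC of
  zero-at-endpoint guides (a count of 1023 at T0 gives exactly −10).
- z-scoring refuses degenerate input (all LFCs equal) rather than
  returning zeros.
- Ties in ranking break by gene score, then symbol — deterministic output.
- Duplicate spacers are an error by default (quantification is an exact
  spacer→guide map); a flag downgrades to first-wins with warning.
- Controls are flagged by the reserved gene label `NO_TARGET`
  (configurable); how controls were labeled in the emulated study's count
  tables is not public, so the convention is this package's.
- IRS proportion percentages falling strictly between the printed integer
  bin edges (e.g. 10.5%) take the lower bin.
- The workflow interface is the `analysis/` scripts plus these exported
  functions; the operations a command-line tool would expose (count,
  score, qc, call-hits, simulate) are exactly the drivers' steps, so no
  separate CLI binary is shipped.

## Problem sizes used in validation

Tests and the acceptance script run the full design at 1,000 genes × 4
guides with 500× depth (single screens in ~1 s), a 200-seed null
calibration at the same scale for false-call rates and depletion-test
uniformity, and a deep noiseless screen (depth 10⁷, dispersion 0) for the
law-of-large-numbers check on neutral LFCs. These sizes were chosen as the
smallest at which the asserted behaviors are clearly resolved.

## Known limitations

No permutation-based gene p-values or FDR (the comparative filter is
threshold-based by design), no copy-number correction, no
mismatch-tolerant matching, and single-orientation read handling. The
recovery results quantify the pipeline under its own generative model;
applying the filter to real screens still warrants the usual orthogonal
validation of hits.
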