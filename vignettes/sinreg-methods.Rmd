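---
title: "Methods: direct-target calling, metagene profiles, and the pausing index"
author: "sinreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: direct-target calling, metagene profiles, and the pausing index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sinreg)
```

This vignette documents the models, conventions and design choices behind
the package: what each stage computes, which knobs matter, what the
synthetic-data generator does and does not emulate, and where the design
was genuinely open.

## Coordinates, anchors, and one convention everywhere

All internal coordinates are 0-based half-open (the BED convention); GTF
input is shifted on read (`start := gtf_start - 1`). The transcription
start site (TSS) of a `+` strand gene is `start`; for a `-` strand gene it
is `end - 1`, the biological 5' end. The transcription end site (TES) is
the opposite extremity. Every window downstream — the peak-assignment
window, the metagene flank, the promoter and gene-body windows of the
pausing index — is defined in *transcription orientation* and mapped to
genomic coordinates per strand, so flipping a gene's strand mirrors all of
its derived windows. Genes may overlap; a peak or base may belong to
several genes, and no deduplication is attempted. One interval per
`gene_id` is used: where an annotation distinguishes transcript-level
start sites the caller must collapse them first, because guessing among
alternative TSSs is not this package's job.

## Direct-target calling

A peak is assigned to a gene when it overlaps, by at least one base, the
window from `upstream_bp` (default 1000) upstream of the TSS through
`past_tes_bp` (default 100) past the TES. One-base overlap suffices; no
summit-containment requirement is imposed, the simplest defensible reading
of a window-assignment rule. Windows are clipped at position 0 (with a
message), never silently truncated.

Differential expression is classified per record: `not_significant` when
`fdr` or `p_value` misses its threshold or `log2fc == 0` (a zero fold
change has no direction); otherwise the sign of `log2fc` is interpreted
through the perturbation polarity. Under a knockdown, a gene that rises
when the factor is removed is *repressed by* the factor; under
overexpression the mapping inverts. Swapping polarity therefore swaps the
repressed/activated labels exactly and leaves `not_significant` fixed — a
property the tests exercise. Default thresholds are FDR < 0.05 and
p < 0.05, matching the knockdown-style analysis; overexpression-style data
conventionally use the stricter FDR < 0.001, passed via
`perturbation_config()`.

A *direct target* is a gene that is both bound (>= 1 assigned peak) and
significant. Two target tables are compared set-wise with
`overlap_summary()`, which reports shared/unique percentages both to one
decimal and integer-rounded, since published figures quote either.

## Metagene matrices

`compute_matrix()` averages per-base signal over `[TSS - flank, TSS +
flank)` (defaults 3 kb, matching common practice for TSS-anchored heat
maps) into consecutive bins of `bin_bp` (default 10 bp, a deepTools-like
resolution; the tools that popularized these plots do not pin a single bin
size, so it is configurable). Rows are oriented 5'→3', column 1 the most
upstream bin. Only the reference-point (TSS-anchored) mode exists;
gene-body-stretched ("scale-regions") matrices are a different estimand
and are out of scope.

Numerical choices:

* Missing signal — uncovered bases, absent chromosomes, bases beyond
  chromosome bounds — contributes **zeros, not NA**, so matrices are
  deterministic and mass conservation holds exactly (`sum(bin means) x
  bin width == window sum`); a per-row clipped-base tally keeps the
  imputation auditable. An unknown chromosome warns rather than errors so
  one misnamed contig cannot kill a thousand-gene matrix.
* Heatmap row order is descending row mean with lexicographic `gene_id`
  tie-break: a deterministic order is required for byte-identical exports,
  and published heat maps do not state their sort.
* The per-bin statistic is the arithmetic mean; a `stat = "median"` option
  exists because the choice is unstated in the literature this package
  follows, but the mean is the default since the average profile is itself
  a mean and the two then compose.

The TSS-localization score (`tss_localization_score()`) is this package's
own quantification of "binding localized at the TSS": mean profile signal
within ±250 bp of the anchor divided by the window-wide mean. It is 1 for
a flat profile and grows with concentration at the anchor. The ±250 bp
core is a choice — wide enough to cover promoter-proximal binding and a
couple of bins of jitter, narrow relative to the 6 kb window — and reports
using it are labelled as an artifact-defined score.

## The pausing index

Per gene, the promoter window is `[TSS - 50, TSS + 50)` and the body
window `[TSS + 300, TES' - 100)`, where `TES'` is the exclusive 3' end —
half-open in transcription orientation, consistent with every other window
in the package (the published endpoint description gives boundaries but
not inclusivity). The *enrichment value* of a window is its **mean**
per-base signal, not the sum: the ratio is then independent of window and
gene length, which is the point of a pausing index. The index is computed
on whatever track is supplied; whether that track is raw coverage or
input-normalized enrichment is the caller's responsibility, and the ratio
is invariant to any positive global scaling of the track (tested).

Degenerate inputs are excluded, not fudged: a gene shorter than
`body_start_offset + body_end_offset` (400 bp at defaults) has an empty or
inverted body window (`excluded_short_gene`); a gene with zero body signal
would have an infinite index that breaks rank statistics
(`excluded_zero_body`). Exclusions are counted and reported rather than
patched with pseudocounts, because a pseudocount would silently turn a
missing-data problem into a fake index value.

Group contrasts use the two-sided Mann–Whitney U test (two-sided because
no sidedness is assumed a priori): U from the rank-sum identity with
midranks for ties; an exact p by full enumeration of rank assignments when
`n_a + n_b <= 12` and no ties (at most C(12,6) = 924 assignments); and
otherwise the normal approximation with tie-corrected variance and
continuity correction, which matches `stats::wilcox.test(exact = FALSE,
correct = TRUE)` to 1e-6 in the tests — `wilcox.test` serves as the
independent cross-check, never the implementation. When every observation
is tied the variance is zero and p = 1 by convention.

## Regulation-strength classification

* |log2FC| bins: `< 2` (soft), `[2, 3]` (middle), `> 3` (hard). Values
  exactly 2 and 3 fall in the middle bin — the only reading consistent
  with quoting "less than 2" and "greater than 3" as strict while naming
  the middle bin "2–3".
* FPKM categories: strong `> 1000`, moderate `[10, 1000]`, low `[1, 10)`,
  silenced `[0, 1)`. Exactly 1 is low and exactly 10 is moderate, closing
  the nominal 9.99–10 gap deterministically; exactly 1000 is moderate.
* Hard-regulation candidates are **activated** direct targets with control
  FPKM `<= 1`. The ceiling is deliberately inclusive ("1 or less") while
  the silenced category is strict (`< 1`); the two rules are implemented
  verbatim side by side rather than reconciled, and both are documented at
  their call sites. Tightening the ceiling can only remove candidates
  (monotonicity, tested).
* Binning uses absolute log2FC for both directions, so repressed genes
  under an overexpression design (negative log2FC) bin identically to
  their knockdown counterparts.

## What the synthetic generator emulates — and what it does not

The generator plants every label the pipeline is supposed to recover, so
recovery is checkable gene by gene, not merely in distribution:

* **Annotation**: non-overlapping genes, lengths uniform on 1–10 kb,
  random strands. Intergenic gaps are drawn from 2.2–4 kb — comfortably
  above the 200 bp minimum a compact genome would suggest — so that a
  promoter peak (width <= 600 bp, centered within ±200 bp of the TSS) can
  never reach a neighbouring gene's assignment window and the planted
  bound/unbound labels remain exactly identifiable.
* **Peaks**: one promoter-proximal peak per bound gene, summit at the TSS
  when it falls inside the peak; optional decoy peaks confined to a
  peak-free chromosome tail, so "decoys only" provably yields zero direct
  targets.
* **Signal**: piecewise-constant per gene — body level `b ~ Gamma(2, 1)`,
  promoter level `r x b` with `r` the planted pausing ratio (defaults 5.0
  for repressed, 1.5 for activated, 1.0 for null genes), a linear per-base
  ramp from promoter to body, background 0.1 elsewhere. With noise off the
  pausing index returns exactly `r`, giving a closed-form ground truth.
  With `noise = TRUE` the gene segments are resampled per base as
  Poisson(value), modelling count noise where it matters; the intergenic
  background stays constant to keep track sizes bounded.
* **Expression tables**: p-values and FDR are planted directly (true
  targets ~ U(0, 0.04), nulls ~ U(0.05, 1)) rather than derived from
  simulated counts — the DE-calling step is upstream of this package, and
  only the statistical shape of its output matters here. |log2FC| is drawn
  per effect class (soft U(0.3, 1.8), mid U(2, 3), hard U(3.2, 6), weights
  0.9/0.06/0.04), strictly inside the corresponding bins so class recovery
  is exact. FPKM is drawn per planted category from a log-normal (medians
  2000/100/3/0.3) by rejection inside the category's interval, so the
  planted category is always recovered. Hard-activated genes are forced
  below FPKM 1; any other activated target that draws `silenced` swaps
  categories with a non-target (or is redrawn from the expressed
  categories when no swap partner exists), so planted hard candidates are
  recovered with zero spurious calls.
* Class counts use largest-remainder rounding, not Bernoulli draws, so
  "fraction_bound = 0.4 of 100 genes" means exactly 40 bound genes.
* All randomness flows from the config seed through stage-specific
  sub-seeds; the caller's RNG state is saved and restored, and an
  identical config yields byte-identical files from `write_dataset()`.

What it does **not** emulate: read-level data (no fragments, no GC or
mappability structure), replicate variability, input/IgG normalization,
overlapping or nested genes, multi-chromosome genomes, and any coupling
between expression level and signal strength. Passing recovery tests
therefore demonstrates the *pipeline arithmetic* is right under the stated
statistical structure — not that the thresholds would behave identically
on a real, messier genome.

## Problem sizes and test design

The suite checks each interval operation against brute-force oracles
(dense per-base arrays, all-pairs overlap loops) on a hundred-plus random
instances of modest size (tracks of tens of intervals on 10–100 kb
chromosomes, up to 1000 peaks), where the naive computation is
unambiguous. The recovery suite uses 500 genes with the default mixture;
the pausing-power study uses 100 genes per group with Poisson noise over
100 seeded replicates; null calibration uses 60-gene replicates over 200
seeds and expects the fraction significant at 0.05 to sit in [0.02, 0.09].
These sizes were chosen so the whole suite runs in a couple of minutes on
one CPU while keeping every Monte-Carlo margin wide relative to its
binomial standard error.

## Known limitations

* One interval per gene: alternative TSSs must be resolved upstream.
* The signal model is strand-agnostic within a window; antisense signal is
  not separated.
* `window_mean` treats out-of-bounds bases as zeros in the denominator;
  for genes hanging off a contig end this biases means toward zero (the
  clipped-base tally exposes how much).
* The Mann–Whitney exact path enumerates only up to 12 combined
  observations; between 13 observations and the asymptotic regime the
  normal approximation is used even though enumeration would be feasible —
  the approximation is already within 0.02 of exact at 10 + 10 (tested).
* Percentages are reported with R's round-half-to-even; published integer
  percentages were evidently conventional rounding, which coincides for
  every quantity reproduced here but is not guaranteed to in general.
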