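---
title: "Models and methods behind mbdqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mbdqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbdqc)
```

`mbdqc` evaluates MBD-capture sequencing libraries from the sequence data
itself. This vignette records the models, the parameter choices and their
rationale, the numerical conventions, and what the bundled simulator can
and cannot tell you about real libraries.

## Fragment reconstruction

A *mapped fragment* is the reference interval covering both sequenced mate
ends and the unsequenced stretch between them: for mates at 0-based
positions `pos1`, `pos2` with aligned lengths `len1`, `len2`, the interval
`[min(pos1, pos2), max(pos1 + len1, pos2 + len2))`. Pairs are kept when

1. both mates are uniquely mapped,
2. they lie on the same reference sequence in inward-pointing orientation,
3. the outer span does not exceed `max_span` (default 400 bp).

Two of these require interpretation. *Unique mapping* is operationalized
as mapping quality ≥ 20 with no secondary alignment record for the mate;
MAPQ 20 is the conventional "better than 99 % confident" cut-off and the
threshold is exposed (`mapq_threshold`). *Within 400 bp* is read as a cap
on the outer span of the reconstructed fragment rather than on the
distance between mate start positions: libraries are sheared to ~200 bp
before capture, so the outer span is the physically meaningful quantity
and 400 bp is twice the shearing target. Both readings agree except for
pathological mate geometries; the flag `max_span` makes the cap explicit.

Duplicates are collapsed on exact `(chrom, start, end)` coordinates only —
orientation is already constrained by the pairing filter — and the copy
count is retained as `multiplicity`, so the collapse conserves the total
fragment count. Every filter writes its rejection tally into the
`filter_tally` attribute so that input pairs can be reconciled against
emitted fragments plus rejections.

Coordinates are 0-based half-open throughout; SAM positions are converted
on input, BED/BEDPE pass through unchanged.

## The Fragment CpG-plot

For a sample with `F_i` non-duplicate fragments containing exactly `i`
CpG dinucleotides, the plot shows `F_i / Σ_i F_i` against `i`. CpGs are
counted as occurrences of the dinucleotide wholly inside `[start, end)` on
the forward strand — the dinucleotide is its own reverse complement, so
counting one strand counts the site exactly once, and a CG whose G falls
outside the interval is not counted. Matching is case-insensitive by
default because soft-masked repeats carry real CpGs (`uppercase_only`
restricts to unmasked sequence); `N` never matches.

Interpretation: mass at `i = 0` is sequence an MBD cannot have bound
through methyl-CpG, so the zero-CpG fraction reads out nonspecific
capture. A pronounced peak at low non-zero `i` means fragments with few
CpGs — hence few methylated CpGs — were still captured, a sensitivity
read-out. Default plots use non-duplicate fragments (`dedup = TRUE`);
with duplicates included each fragment is weighted by its multiplicity.

Fragment length confounds between-study comparison — longer fragments
carry more CpGs — so the plot is a within-experiment diagnostic; no length
normalization is attempted. Display truncation of the x-axis is a plotting
option only and never alters the table.

## Enrichment profiles against independent methylation calls

Independent per-CpG methylation degrees come either from RRBS-style
counts, where the two strand records of one CpG are summed and keyed to
the forward-strand C and loci need coverage ≥ 20 (the conventional
resolution threshold, exposed as `min_cov`), or from array beta values,
which are treated as already strand-combined with unlimited coverage.

Degrees are binned into `[k·w, (k+1)·w)` with the top bin closed at 1;
`w = 0.02` for RRBS-like and `w = 0.05` for array-like sources. A degree
exactly on an interior edge goes to the upper bin (deterministic
tie-break); the division is nudged by `1e-9` before flooring so that
edges survive binary floating point (e.g. `0.06 / 0.02`).

Each deduplicated fragment contributes incidences to the bins of the
assessed CpGs it contains (a CpG is *in* a fragment when its forward C
position lies in `[start, end)`). The profiles are CpG-oriented: by
default every fragment–CpG containment pair is one incidence
(`semantics = "cpg"`). Under this convention, uniform (nonspecific)
capture reproduces the background profile *exactly in expectation*, which
is what makes the ratio a calibrated null — the package's null-calibration
test relies on it. The alternative `semantics = "set"` counts each
(fragment, bin) pair once, bounding any single fragment's influence by the
number of bins; its cost is a systematic depression of bins whose CpGs
cluster densely (a fully methylated island packs many same-bin CpGs into
one fragment), which biases exactly the bins a capture experiment cares
about. Both are implemented; `"cpg"` is the default for the calibration
reason above.

The background profile bins every assessed CpG once. The enrichment ratio
divides kit by background fractions per bin; zero-background bins yield
`NA`, not infinity, and are omitted from the *onset*: the first bin index
from which the ratio is ≥ 1 in every higher occupied bin. Because
fractions sum to one for kit and background alike, fractions and ratios
are invariant under any uniform replication of the fragment set — the
profiles compare kits of wildly different yields on equal footing.

The onset is a discrete extreme-order statistic: one under-sampled bin
whose ratio dips below 1 pushes the onset up. It is therefore only as
stable as the sparsest occupied bin, and on small CpG tables it carries
replicate-to-replicate noise of several bins. The zero-CpG fraction of the
Fragment CpG-plot, by contrast, is a plain proportion and is stable at
any practical depth; when the two disagree on a ranking, trust the
fraction first. The acceptance script quantifies both behaviours (success
rates of the archetype contrast over 100 replicates).

## The simulator

The simulator generates the full chain — genome, methylation landscape,
capture, sequencing, bisulfite observation — from one seeded generator, so
identical parameters and seed reproduce an experiment bit-exactly. Its
defaults are the package's reference study conditions:

| parameter | default | rationale |
|---|---|---|
| genome length | 100 kb | smallest scale at which all 50 bins of the 2 % profile are populated |
| island fraction | 0.15 | order of the genomic share of island-proximal sequence |
| island length | Gamma, mean 1 kb | typical annotated island lengths |
| C→G transition | 0.05 background, 0.25 island | ~1 CpG per 100 bp outside islands, ~7.5 per 100 bp inside |
| GC content | 0.40 background, 0.60 island | genome-wide vs island-typical composition |
| background degrees | Beta(9, 1) | most non-island CpGs heavily methylated (mean 0.9) |
| island mixture | π = 0.3 methylated; Beta(9, 1) vs Beta(1, 9) | bimodal, mostly hypomethylated islands |
| fragment length | truncated normal, mean 200, sd 50, bounds [50, 400] | sonication target of enrichment libraries |
| mate length | 45 bp | short paired-end reads |
| RRBS coverage | Poisson, mean 30 | puts the coverage-20 filter in a realistic regime |

The genome is a first-order dinucleotide chain whose C→G transition
probability is elevated inside islands. Methylation is island-coherent:
each island draws its mixture component *once* and all its CpGs draw
degrees from that component's Beta. This mirrors island-level promoter
silencing and it matters for the diagnostics — if components were drawn
per CpG, every island would be a salt-and-pepper mix and any island
CpG's neighbours would saturate capture regardless of its own degree,
erasing the depletion/enrichment contrast the profiles exist to measure.

Capture treats each methylated CpG as an independent binding chance:
a molecule with `m` methylated CpGs (re-sampled per molecule by
Bernoulli(degree) per contained CpG — allelic and cellular heterogeneity)
is captured with probability `p(m) = ε + (1 − ε)(1 − (1 − q)^m)`. The
nonspecific floor ε is the specificity axis; the per-CpG success `q` the
sensitivity axis. This two-parameter archetype is a deliberate stand-in:
no quantitative affinity curve is available for any real MBD, and two
monotone parameters are the minimum that spans the specificity ×
sensitivity plane the diagnostics measure. One behavioural consequence is
documented honestly: archetypes separate strongly in the zero-CpG
fraction, but their enrichment-ratio profiles all cross the background
near the mean methylated load, so onset differences between archetypes
are small (a few bins) even when their `q` differ tenfold.

Sequencing draws `n_reads` fragments from the captured pool with
replacement — a single-knob proxy for PCR amplification plus flow-cell
sampling, rather than an explicit cycle-count model. Small pools therefore
produce high duplicate fractions, reproducing the signature of inefficient
capture; the non-duplicate count follows the occupancy law
`K(1 − (1 − 1/K)^n)` for a pool of size `K`, which the tests verify.
Bisulfite observation is Binomial(Poisson(mean coverage), degree) per CpG;
zero-coverage CpGs are absent from the output, as they would be from a
caller's table.

What the simulator does *not* emulate: base-call errors and quality
strings, mapper behaviour (fragments are emitted as already-mapped
intervals; the three uniqueness/orientation/span filters are exercised by
constructed alignment fixtures instead), salt-elution chemistry,
non-CpG methylation, and real genomic repeat structure. Passing tests
therefore demonstrate that the *computations* are correct and that the
diagnostics respond to capture parameters in the expected direction — not
that any particular real kit will separate as cleanly as two archetypes
with tenfold parameter differences.

## Numerical conventions and test scales

* Percentages round half away from zero to one decimal, matching how
  yield tables are conventionally printed (`round()`'s half-to-even would
  turn 57.45 into 57.4).
* Histogram and profile fractions must sum to 1 within `1e-9`; tests
  assert bit-identical invariance under sevenfold fragment replication,
  which holds because IEEE division of `7c` by `7T` and of `c` by `T`
  round the same real number.
* All simulation stages accept an explicit seed or inherit the current
  RNG stream; `simulate_experiment()` seeds once and threads the stream
  through every stage.
* Test problem sizes: oracle comparisons run on a 10 kb random sequence
  with 500 fragments and on a 50-fragment/200-CpG table (exhaustive
  nested-loop oracles stay tractable); calibration and contrast checks use
  the 100 kb default genome with 50,000 molecules per kit and, for the
  archetype contrast, 100 seeded replicates — sized so the whole suite
  completes in a few minutes on one core while every profile bin stays
  populated.

## Known limitations

* The onset statistic is noisy by construction (see above); rankings
  should lean on the zero-CpG fraction when tables are small.
* The capture archetype is phenomenological; it cannot express
  sequence-context preferences of particular MBDs or salt-dependent
  elution profiles.
* Fragment CpG-plots are not comparable across studies with different
  shearing distributions, and are unsuitable for short single-end reads
  that do not span the captured fragment.
* Array-like methylation tables are taken at face value (no
  normalization); RRBS tables are trusted after the coverage filter —
  no strand-bias or conversion-efficiency modelling.
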