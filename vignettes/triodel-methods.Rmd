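---
title: "Detecting rare inherited biallelic gene deletions in trios from read depth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting rare inherited biallelic gene deletions in trios from read depth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triodel)
```

## The problem

A child who inherits a deleted copy of the same gene from each parent has no
functional copy at all — a "human knockout". When the gene causes an
autosomal recessive (AR) disease, such homozygous whole-gene deletions are
immediately diagnostic (the classic example is the recurrent *NPHP1*
deletion in nephronophthisis), yet they are easy to miss: SNV/indel callers
do not see them and exome-style CNV callers have poor specificity.

triodel implements a deliberately simple, depth-only discovery strategy for
whole-genome sequencing cohorts organised as parent–child trios:

1. measure the mean read depth of each autosomal gene region in every
   sample;
2. normalize to a diploid-scaled dosage $d$ and call integer copy numbers;
3. keep loci where the proband is CN 0 and *both* parents are CN 1
   (the 0-1-1 pattern — the only configuration consistent with an inherited
   biallelic deletion);
4. keep loci whose heterozygous-deletion frequency in a control cohort
   (*fdel*) is below 0.5%;
5. merge contiguous region-level calls into distinct deletion events and
   keep events of at least 8 kb;
6. annotate with gene, OMIM, segmental-duplication and autozygosity (ROH)
   evidence.

Loci that survive are then re-queried in probands without parental data
(the targeted singleton screen), and probands at CN 0 whose parents cannot
both be carriers are flagged as de novo candidates.

## The dosage model

For sample $s$ and region $r$ with observed mean depth $y_{sr}$, the
two-stage median normalization computes

$$ d_{sr} \;=\; 2\,\frac{y_{sr}/m_s}{c_r}, \qquad
   m_s = \operatorname{median}_r\, y_{sr}, \qquad
   c_r = \operatorname{median}_{s \in \text{ref}}\, y_{sr}/m_s . $$

Stage 1 removes library size exactly (multiplying one sample's depths by a
constant leaves its $d$ unchanged); stage 2 removes region-specific
mappability/GC effects. Medians are used because the pipeline hunts
deletions that are *rare*: a handful of carriers cannot move a median.
The flip side is a real limitation — a region deleted in the majority of
the reference cohort would have its baseline dragged down and carriers
would be mis-scaled. Such regions cannot pass the < 0.5% frequency filter
anyway, so the bias is accepted and documented rather than modelled.

Copy numbers are the nearest integer to $d$: CN 0 iff $d < 0.5$, CN $k$ iff
$k - 0.5 \le d < k + 0.5$, capped at `cn_max = 4` (gains are not the
subject). A dosage exactly on an edge goes upward, so $d = 0.5$ calls CN 1
— the conservative direction for a homozygous-deletion screen. Regions
whose reference baseline $c_r$ falls below `min_region_median = 0.1` carry
no signal in anyone (unmappable or uncovered) and are masked; masked
regions propagate as `NA` and can never produce a call downstream. No
per-cell quality score is emitted; the distance $|d - \mathrm{CN}|$ is
attached for triage instead.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `max_fdel` | 0.005 | fraction | discovery rarity filter, strict `<` |
| `min_size` | 8000 | bp | event size filter, inclusive `>=` |
| `max_gap` | 100000 | bp | merge gap: gene regions are not tiling, adjacent deleted genes in one CNV are separated by intergenic sequence; 100 kb bridges that without joining independent events |
| `min_region_median` | 0.1 | dosage | masks regions with no usable coverage anywhere |
| `cn_max` | 4 | copies | cap; amplification detail out of scope |
| `roh_min` | 2000000 | bp | conventional "large ROH" threshold for autozygosity |

Boundary semantics are deliberate and tested: fdel exactly at the threshold
is *removed* (strict `<`), an event of exactly 8000 bp is *retained*
(inclusive), and unknown fdel fails closed — a call at a region with no
control data is dropped with a warning, because rarity cannot be asserted
without controls.

Filter order is frequency → merge → size: fdel is a per-region quantity so
it must be applied before region calls lose their identity in merging,
while size is a property of the merged event. Merging chains calls that are
consecutive among the *unmasked* regions of the region set (an intervening
unmasked region that escaped calling breaks the chain; a masked one does
not) with genomic gap at most `max_gap`. Events with identical spans across
samples are consolidated into one "distinct" deletion listing all
supporting samples; spans differing by any coordinate stay distinct. This
is the simplest reproducible operationalisation of "distinct deletions",
and the one the per-sample/oracle tests pin down. ROH evidence requires
full containment of the event in a run of at least `roh_min` — a deletion
inherited identical-by-descent sits inside the surrounding homozygous tract
— and a sample without ROH data is reported as unknown (`NA`), never
`FALSE`.

De novo candidates require the non-transmitting parent at CN ≥ 2, not
merely "≠ 1", so a single-copy gain in a parent cannot mimic de novo loss;
a proband at CN 0 with both parents at CN ≥ 2 would need two independent
events and is only logged (attribute `double_de_novo`), since confirming
such a call needs read-level review that is out of scope.

## What the simulator emulates — and what it does not

`simulate_cohort()` / `simulate_trios()` generate the stated world used by
every end-to-end test:

* founder genotypes at each spiked deletion are Hardy–Weinberg draws at the
  event's allele frequency $p$; trio children inherit one allele from each
  parent uniformly at random (Mendelian by construction unless a de novo
  rate is set);
* expected mean depth of a cell is
  $\lambda \, g_s \, e_r \, \mathrm{CN}/2$ with $\lambda = 30$ (typical
  WGS), lognormal sample effects $g_s$ ($\sigma = 0.1$, library-size
  spread) and region effects $e_r$ ($\sigma = 0.3$, mappability/GC spread —
  large enough that skipping stage-2 normalization breaks calling);
* a homozygously deleted cell gets a floor of 1% of its expected diploid
  depth, standing in for mismapped reads at low-copy repeats (the loci that
  dominate recurrent deletions lie in segmental duplications);
* region effects are a property of the *region*, so two cohorts simulated
  from the same config share them — this is what makes a simulated control
  cohort usable as a normalization reference for a simulated case cohort;
* noise is applied on the read-count scale: the region's read count is
  drawn Poisson or negative-binomial with mean
  $\mu \cdot \text{length}/\text{read length}$ (read length 150) and
  converted back to a mean depth. Applying count noise to the mean depth
  itself (a tempting simplification) gives a dosage standard deviation of
  ≈ 0.37 at CN 2 and λ = 30 — a caller working on such data could never
  reach the 99% cell-level accuracy that region-averaged real data
  supports, so the simplification was rejected. The negative-binomial size
  default of 400 puts the coefficient of variation of a 20 kb region's mean
  depth at ≈ 5%, typical of normalized WGS region depth.

Default synthetic regions are 20 kb gene spans separated by 30 kb — a
three-region deletion spans 120 kb, inside the 21–750 kb range reported
for real morbid events.

The simulator does **not** model GC bias, read-level artefacts, breakpoint
micro-homology, X chromosome, or mosaicism; and its region effects are
independent across regions, whereas real mappability is spatially
correlated. A green recovery test therefore establishes that the
*arithmetic* of the pipeline is right under realistic noise magnitudes —
not that the caller is robust to every artefact of real sequencing.

## Degenerate inputs and numerical choices

* A sample whose median depth is 0 has no usable coverage: normalization
  refuses it by name rather than emitting infinities.
* Uncovered bases inside a region contribute 0 with the region length as
  denominator, so absent coverage depresses the mean instead of vanishing.
* Coordinates are 0-based half-open everywhere internally (BED
  convention); the event report adds a 1-based inclusive column for
  human readers. Chromosome labels accept and strip a leading `chr`.
* Interval intersection is half-open with a 1 bp minimum; ROH uses
  containment, not intersection (see above).
* Ties in merging cannot arise: chains are deterministic given the region
  order, and event tables sort by (chromosome as integer, start, end,
  pattern).

## Known limitations

No GC correction; no HMM segmentation across regions (single-region events
below depth resolution are invisible); breakpoints are region boundaries,
not base-pair accurate; the normalization bias at commonly deleted regions
described above; de novo candidates are flagged, not confirmed. These match
the scope of the depth-only strategy the package implements.
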