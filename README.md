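# triodel

Depth-based discovery of rare inherited biallelic (homozygous) gene
deletions in parent–child trios from whole-genome sequencing.

## What problem it solves, and for whom

A proband who inherits a deleted copy of the same gene from both parents
carries no functional copy — for an autosomal recessive (AR) disease gene
this is immediately diagnostic (the textbook case is the recurrent *NPHP1*
whole-gene deletion in nephronophthisis), yet whole-gene deletions are
routinely missed by SNV/indel pipelines. triodel is for analysts of
trio-based rare-disease WGS cohorts who want a transparent, depth-only
screen for such events, with a control cohort supplying deletion
frequencies and a simulator supplying ground truth for validation.

## The method

For sample $s$ and region $r$ (autosomal gene regions, BED-style 0-based
half-open intervals) with mean per-base depth $y_{sr}$, dosage is

$$ d_{sr} = 2\,\frac{y_{sr}/m_s}{c_r},\quad
   m_s = \mathrm{median}_r\,y_{sr},\quad
   c_r = \mathrm{median}_{s\in\mathrm{ref}}\,(y_{sr}/m_s), $$

and copy number is the nearest integer to $d$ (CN 0 iff $d<0.5$; ties go
up; capped at 4). The discovery filters are then

1. **inheritance**: proband CN 0, father CN 1, mother CN 1 (the "0-1-1"
   pattern compatible with AR inheritance);
2. **rarity**: heterozygous-deletion frequency in the control cohort
   *fdel* $< 0.5\%$ (strict);
3. **size**: contiguous region calls are merged into events (gap
   ≤ 100 kb), and events of at least 8000 bp are kept (inclusive).

Surviving events are annotated with gene symbols, OMIM-morbid / AR flags,
segmental-duplication overlap and per-sample containment in runs of
homozygosity ≥ 2 Mb. Discovered loci feed a targeted screen of probands
without parental data, and probands at CN 0 with exactly one non-carrier
parent (CN ≥ 2) are flagged as de novo candidates.

## Worked example

A desk-scale cohort: 250 trios and 600 controls over 80 synthetic gene
regions, with one three-region deletion segregating at allele frequency
0.12. (At desk scale a truly rare allele almost never produces a
homozygous child, so the demo uses a common spike and relaxes the rarity
threshold accordingly; the defaults are for cohort-scale data.)

```r
library(triodel)
regions  <- sim_regions(80)
cfg      <- sim_config(n_trios = 250, n_controls = 600, regions = regions,
                       spiked_events = list(list(
                         region_ids = c("R00013", "R00035", "R00057"),
                         p = 0.12)),
                       seed = 42)
trios    <- simulate_trios(cfg)
controls <- simulate_cohort(cfg)
res <- run_ar_discovery(pipeline_config(regions, trios$trios, trios$depth,
                                        controls$depth, max_fdel = 0.25))
res$log
#>              stage  n_in n_out
#> 1       trio_0_1_1 20000     6
#> 2 frequency_filter     6     6
#> 3            merge     6     1
#> 4      size_filter     1     1
res$events
#> deletion_events: 1 event(s)
#>   chrom   start     end   size n_regions n_samples             pattern
#> 1    13 1000000 1120000 120000         3         2 inherited_biallelic
#>    fdel_max
#> 1 0.2216667
```

Reading the output: 250 trios × 80 regions = 20,000 (trio, region) pairs
were scanned and 6 showed the 0-1-1 pattern — the two true homozygous
probands (`sum(trios$truth$trio_status$is_011)` is 2) each called at the
three member regions of the deletion. All 6 survive the rarity filter
(realized control fdel 0.2217 = 133 heterozygous carriers / 600 controls,
below the relaxed 0.25 threshold), merge into **one distinct event** with
the true 120 kb span (regions R00013–R00057 on chromosome 13, supported by
both probands), and pass the 8 kb size filter.

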