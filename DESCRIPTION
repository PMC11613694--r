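Package: triodel
Title: Depth-Based Discovery of Rare Inherited Biallelic Gene Deletions in Trios
Version: 0.1.0
Authors@R: person("triodel", "maintainers", email = "triodel@example.org",
    role = c("aut", "cre"))
Description: A read-depth copy-number pipeline for detecting rare inherited
    homozygous (biallelic) gene deletions in parent-child trios from whole
    genome sequencing. Computes per-region mean-coverage matrices, normalizes
    them to diploid-scaled dosage with a two-stage median scheme, calls
    integer copy numbers, filters trio genotype patterns (proband CN 0 with
    both parents CN 1), estimates heterozygous-deletion frequencies in a
    control cohort, merges contiguous region-level calls into distinct
    deletion events with size and rarity filters, annotates events with gene,
    segmental-duplication and autozygosity (run-of-homozygosity) evidence,
    and includes a cohort simulator with Hardy-Weinberg founder genotypes and
    Mendelian transmission that provides ground truth for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
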