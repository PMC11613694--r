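# 6 regions on chrom 1 (20 kb each, small gaps), 1 on chrom 2
ev_regions <- region_set(
  sprintf("r%d", 1:7),
  c(rep("1", 6), "2"),
  c(0, 22000, 45000, 600000, 1200000, 1226000, 5000),
  c(20000, 40000, 65000, 620000, 1220000, 1246000, 25000),
  sprintf("G%d", 1:7))

test_that("adjacent called regions chain into one event under max_gap", {
  calls <- data.frame(sample_id = "P1", region_id = c("r1", "r2", "r3"),
                      stringsAsFactors = FALSE)
  ev <- merge_contiguous_calls(calls, ev_regions)  # gaps 2 kb and 5 kb
  expect_equal(nrow(ev), 1)
  expect_equal(ev$region_ids[[1]], c("r1", "r2", "r3"))
  expect_equal(c(ev$start, ev$end, ev$size), c(0L, 65000L, 65000L))
})

test_that("a gap beyond max_gap or an intervening uncalled region splits", {
  calls <- data.frame(sample_id = "P1", region_id = c("r3", "r4"),
                      stringsAsFactors = FALSE)
  # gap r3 -> r4 is 535 kb
  expect_equal(nrow(merge_contiguous_calls(calls, ev_regions)), 2)
  expect_equal(nrow(merge_contiguous_calls(calls, ev_regions,
                                           max_gap = 600000)), 1)

  # r4 uncalled between r3 and r5 blocks chaining even under a huge gap
  calls <- data.frame(sample_id = "P1", region_id = c("r3", "r5"),
                      stringsAsFactors = FALSE)
  expect_equal(nrow(merge_contiguous_calls(calls, ev_regions,
                                           max_gap = 5e6)), 2)
  # ... unless r4 is masked, in which case r3 and r5 are order-adjacent
  expect_equal(nrow(merge_contiguous_calls(calls, ev_regions, max_gap = 5e6,
                                           masked = "r4")), 1)

  expect_error(merge_contiguous_calls(
    data.frame(sample_id = "P1", region_id = "nope"), ev_regions),
    "unknown region")
})

test_that("identical spans consolidate across samples; others stay distinct", {
  calls <- data.frame(sample_id = c("P1", "P1", "P2", "P2", "P3"),
                      region_id = c("r1", "r2", "r1", "r2", "r1"),
                      stringsAsFactors = FALSE)
  ev <- merge_contiguous_calls(calls, ev_regions)
  expect_equal(nrow(ev), 2)
  spans <- paste(ev$chrom, ev$start, ev$end)
  expect_setequal(spans, c("1 0 40000", "1 0 20000"))
  expect_setequal(ev$sample_ids[[which(spans == "1 0 40000")]], c("P1", "P2"))
  expect_equal(ev$sample_ids[[which(spans == "1 0 20000")]], "P3")
})

test_that("merging equals the independent gap-walk oracle on random calls", {
  set.seed(51)
  n_regions <- 30
  regs <- region_set(sprintf("q%02d", 1:n_regions),
                     rep(c("1", "2", "3"), each = 10),
                     rep(seq(0, by = 60000, length.out = 10), 3),
                     rep(seq(0, by = 60000, length.out = 10) +
                           sample(c(20000, 45000), 10, TRUE), 3))
  for (rep in 1:25) {
    calls <- data.frame(
      sample_id = sprintf("S%d", sample(1:6, 40, TRUE)),
      region_id = regs$region_id[sample(n_regions, 40, TRUE)],
      stringsAsFactors = FALSE)
    calls <- unique(calls)
    masked <- if (rep %% 3 == 0) sample(regs$region_id, 4) else character()
    gap <- sample(c(15000, 40000, 100000), 1)
    got <- flatten_events(merge_contiguous_calls(calls, regs, max_gap = gap,
                                                 masked = masked))
    want <- oracle_merge(calls, regs, max_gap = gap, masked = masked)
    rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("per-sample events are disjoint, sorted, and conserve bases", {
  set.seed(52)
  regs <- sim_regions(40, region_length = 10000, spacing = 5000, n_chrom = 4)
  calls <- data.frame(sample_id = "P1",
                      region_id = sample(regs$region_id, 15),
                      stringsAsFactors = FALSE)
  ev <- merge_contiguous_calls(calls, regs)
  ord <- order(as.integer(ev$chrom), ev$start)
  expect_equal(ord, seq_len(nrow(ev)))
  by_chrom <- split(ev, ev$chrom)
  for (sub in by_chrom)
    if (nrow(sub) > 1)
      expect_true(all(sub$start[-1] >= sub$end[-nrow(sub)]))
  # union conservation: every called region's bases lie inside the events
  ridx <- match(calls$region_id, regs$region_id)
  for (k in ridx) {
    inside <- any(ev$chrom == regs$chrom[k] & ev$start <= regs$start[k] &
                    regs$end[k] <= ev$end)
    expect_true(inside)
  }
})

test_that("size filter is inclusive at min_size and monotone", {
  ev <- deletion_events(chrom = c("1", "1", "1"),
                        start = c(0L, 0L, 0L),
                        end = c(7999L, 8000L, 750000L),
                        region_ids = list("a", "b", "c"),
                        sample_ids = list("s", "s", "s"),
                        pattern = "cn0", fdel_max = NA_real_)
  kept <- apply_size_filter(ev)
  expect_setequal(kept$size, c(8000L, 750000L))
  expect_true(21000 >= 8000)  # the smallest reported morbid event passes
  expect_error(apply_size_filter(ev, 0), "positive")
  prev <- apply_size_filter(ev, 1)
  for (ms in c(5000, 8000, 1e5, 1e6))
    expect_true(all(apply_size_filter(ev, ms)$size %in% prev$size))
})

test_that("annotation flags genes, segdups and ROH containment", {
  calls <- data.frame(sample_id = c("P1", "P1", "P2"),
                      region_id = c("r5", "r6", "r7"),
                      stringsAsFactors = FALSE)
  ft <- data.frame(region_id = sprintf("r%d", 1:7),
                   fdel = c(0.1, 0.1, 0.1, 0.1, 0.001, 0.004, 0.002),
                   n_het = 1L, n_hom = 0L, n_controls = 1000L)
  ev <- merge_contiguous_calls(calls, ev_regions, fdel = ft)
  expect_equal(sort(ev$fdel_max), c(0.002, 0.004))
  annot <- annotation_tables(
    gene_flags = data.frame(gene_symbol = c("G5", "G6", "G7"),
                            omim_morbid = c(TRUE, FALSE, FALSE),
                            omim_ar = c(TRUE, FALSE, FALSE)),
    segdup = data.frame(chrom = "1", start = 1150000L, end = 1201000L),
    roh = list(P1 = data.frame(chrom = "1", start = 1000000L, end = 4100000L)))
  ann <- annotate_events(ev, annot, ev_regions)
  big <- ann[ann$chrom == "1", ]  # r5+r6 event for P1
  expect_setequal(big$genes[[1]], c("G5", "G6"))
  expect_true(big$omim_morbid && big$omim_ar)
  expect_true(big$segdup_overlap)  # [1.2Mb,1.246Mb) vs [1.15Mb,1.201Mb): 1 kb
  expect_true(big$roh_overlap[[1]][["P1"]])  # contained in a 3.1 Mb run
  other <- ann[ann$chrom == "2", ]
  expect_false(other$omim_morbid)
  expect_false(other$segdup_overlap)
  expect_true(is.na(other$roh_overlap[[1]][["P2"]]))  # no ROH data: unknown

  # a run shorter than roh_min gives FALSE even when it contains the event
  annot$roh$P1 <- data.frame(chrom = "1", start = 1190000L, end = 1300000L)
  ann2 <- annotate_events(ev, annot, ev_regions)
  expect_false(ann2[ann2$chrom == "1", ]$roh_overlap[[1]][["P1"]])
})

test_that("morbid enrichment tabulates counts and proportions by strata", {
  annot <- annotation_tables(gene_flags = data.frame(
    gene_symbol = c("M1", "M2", "N1", "N2"),
    omim_morbid = c(TRUE, TRUE, FALSE, FALSE),
    omim_ar = c(TRUE, FALSE, FALSE, FALSE)))
  # morbid genes only in the rare & large stratum, by construction
  rec <- data.frame(
    gene_symbol = c("M1", "M2", "N1", "N2", "N1", "N2"),
    fdel = c(0.001, 0.002, 0.001, 0.05, 0.06, 0.07),
    size = c(50000, 100000, 3000, 60000, 2000, 1000))
  tab <- morbid_enrichment(rec, annot, fdel_bins = 0.005, size_bins = 8000)
  expect_equal(nrow(tab), 4)
  cell <- function(fd, sz) tab[tab$fdel_bin == fd & tab$size_bin == sz, ]
  rare_large <- cell("[-Inf,0.005)", "[8000,Inf)")
  expect_equal(rare_large$n_morbid, 2L)
  expect_equal(rare_large$n_nonmorbid, 0L)
  expect_equal(rare_large$prop_morbid, 1)
  expect_true(is.na(cell("[0.005,Inf)", "[-Inf,8000)")$prop_morbid) ||
                cell("[0.005,Inf)", "[-Inf,8000)")$n_morbid +
                cell("[0.005,Inf)", "[-Inf,8000)")$n_nonmorbid > 0)
  # rare & large has the maximal morbid proportion
  expect_true(all(rare_large$prop_morbid >=
                    tab$prop_morbid[!is.na(tab$prop_morbid)]))

  expect_equal(nrow(morbid_enrichment(rec[0, ], annot)), 0)
  expect_error(morbid_enrichment(rec, annot, fdel_bins = c(0.01, 0.001)),
               "strictly increasing")
})
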