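# Independent brute-force oracles. These deliberately share no code with the
# package implementations: plain loops, no vectorized shortcuts.

oracle_mean_depth <- function(cov, region) {
  total <- 0
  v <- cov[[as.character(region$chrom)]]
  for (pos0 in region$start:(region$end - 1L)) {
    i <- pos0 + 1L
    total <- total + if (i <= length(v)) v[i] else 0
  }
  total / (region$end - region$start)
}

# two-pass median normalization recomputed cell by cell
oracle_normalize <- function(depths, reference_samples = rownames(depths),
                             min_region_median = 0.1) {
  r1 <- depths
  for (s in rownames(depths)) r1[s, ] <- depths[s, ] / median(depths[s, ])
  d <- r1
  mask <- logical(ncol(depths))
  for (j in seq_len(ncol(depths))) {
    c_r <- median(r1[reference_samples, j])
    mask[j] <- c_r < min_region_median
    d[, j] <- 2 * r1[, j] / c_r
  }
  list(d = d, mask = mask)
}

oracle_trio_scan <- function(cn, trios, type = c("biallelic", "de_novo")) {
  type <- match.arg(type)
  mask <- attr(cn, "mask")
  if (is.null(mask)) mask <- rep(FALSE, ncol(cn))
  hits <- list()
  for (i in seq_len(nrow(trios$trios))) {
    tr <- trios$trios[i, ]
    for (j in seq_len(ncol(cn))) {
      if (mask[j]) next
      p <- cn[tr$proband_id, j]; f <- cn[tr$father_id, j]
      m <- cn[tr$mother_id, j]
      if (any(is.na(c(p, f, m)))) next
      ok <- if (type == "biallelic") p == 0 && f == 1 && m == 1
            else p == 0 && ((f >= 2 && m <= 1) || (m >= 2 && f <= 1))
      if (ok) hits[[length(hits) + 1L]] <-
          data.frame(proband_id = tr$proband_id, region_id = colnames(cn)[j],
                     stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(proband_id = character(), region_id = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

oracle_fdel <- function(cn) {
  mask <- attr(cn, "mask")
  if (is.null(mask)) mask <- rep(FALSE, ncol(cn))
  rows <- list()
  for (j in seq_len(ncol(cn))) {
    if (mask[j]) next
    het <- 0L; hom <- 0L
    for (i in seq_len(nrow(cn))) {
      if (is.na(cn[i, j])) next
      if (cn[i, j] == 1) het <- het + 1L
      if (cn[i, j] == 0) hom <- hom + 1L
    }
    rows[[length(rows) + 1L]] <- data.frame(
      region_id = colnames(cn)[j], fdel = het / nrow(cn),
      n_het = het, n_hom = hom, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# independent gap-walk merger: connected components of the "chainable"
# relation, one sample at a time; returns spans keyed by sample
oracle_merge <- function(calls, regions, max_gap = 100000, masked = character()) {
  unmasked_ids <- regions$region_id[!regions$region_id %in% masked]
  spans <- list()
  for (s in unique(calls$sample_id)) {
    rids <- calls$region_id[calls$sample_id == s]
    rids <- rids[!rids %in% masked]
    idx <- sort(match(rids, regions$region_id))
    if (!length(idx)) next
    groups <- list(idx[1])
    for (k in idx[-1]) {
      last <- groups[[length(groups)]]
      prev <- last[length(last)]
      same_chrom <- regions$chrom[prev] == regions$chrom[k]
      adjacent <- sum(regions$region_id[seq_len(nrow(regions))] %in%
                        unmasked_ids &
                        seq_len(nrow(regions)) > prev &
                        seq_len(nrow(regions)) < k) == 0
      gap_ok <- (regions$start[k] - regions$end[prev]) <= max_gap
      if (same_chrom && adjacent && gap_ok)
        groups[[length(groups)]] <- c(last, k)
      else groups[[length(groups) + 1L]] <- k
    }
    for (g in groups)
      spans[[length(spans) + 1L]] <- data.frame(
        sample_id = s, chrom = regions$chrom[g[1]],
        start = min(regions$start[g]), end = max(regions$end[g]),
        n_regions = length(g), stringsAsFactors = FALSE)
  }
  if (!length(spans))
    return(data.frame(sample_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_regions = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, spans)
  out[order(out$sample_id, as.integer(out$chrom), out$start), , drop = FALSE]
}

# per-sample spans of the package merger, for comparison with oracle_merge
flatten_events <- function(events) {
  if (!nrow(events))
    return(data.frame(sample_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_regions = integer(), stringsAsFactors = FALSE))
  rows <- list()
  for (i in seq_len(nrow(events)))
    for (s in events$sample_ids[[i]])
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, chrom = events$chrom[i], start = events$start[i],
        end = events$end[i], n_regions = length(events$region_ids[[i]]),
        stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  out <- out[order(out$sample_id, as.integer(out$chrom), out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- random instance generators -------------------------------------------

random_cn_matrix <- function(n_samples, n_regions,
                             probs = c(0.03, 0.07, 0.8, 0.07, 0.03)) {
  m <- matrix(sample(0:4, n_samples * n_regions, replace = TRUE, prob = probs),
              n_samples, n_regions,
              dimnames = list(sprintf("S%03d", seq_len(n_samples)),
                              sprintf("R%03d", seq_len(n_regions))))
  storage.mode(m) <- "integer"
  m
}

random_trio_set <- function(n_trios) {
  trio_set(data.frame(
    family_id = sprintf("F%03d", seq_len(n_trios)),
    proband_id = sprintf("S%03d", seq(1, 3 * n_trios, by = 3)),
    father_id = sprintf("S%03d", seq(2, 3 * n_trios, by = 3)),
    mother_id = sprintf("S%03d", seq(3, 3 * n_trios, by = 3)),
    stringsAsFactors = FALSE))
}

random_events <- function(n) {
  start <- sort(sample.int(1e7, n)) * 10L
  deletion_events(
    chrom = as.character(sample(1:22, n, replace = TRUE)),
    start = start, end = start + sample.int(5e5, n),
    region_ids = lapply(seq_len(n), function(i)
      sprintf("R%05d", sample.int(99999, sample(1:4, 1)))),
    sample_ids = lapply(seq_len(n), function(i)
      sprintf("S%04d", sample.int(9999, sample(1:3, 1)))),
    pattern = sample(c("inherited_biallelic", "cn0"), n, replace = TRUE),
    fdel_max = ifelse(runif(n) < 0.2, NA_real_, round(runif(n, 0, 0.02), 6)))
}
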