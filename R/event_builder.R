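#' Deletion events
#'
#' A deletion event is the pipeline's unit of reporting: one or more
#' contiguous called regions merged into a single genomic span (0-based
#' half-open), with the samples (or trio probands) supporting it, the
#' maximum control-cohort fdel over its member regions, and annotations.
#' Events are stored as a data frame with list columns for the multi-valued
#' fields.
#'
#' @param chrom,start,end,pattern,fdel_max vectors, one element per event.
#' @param region_ids,sample_ids lists of character vectors, one per event.
#' @return A \code{deletion_events} data frame with columns \code{chrom},
#'   \code{start}, \code{end}, \code{size}, \code{region_ids} (list),
#'   \code{sample_ids} (list), \code{pattern}, \code{fdel_max}, plus (after
#'   [annotate_events()]) \code{genes} (list), \code{omim_morbid},
#'   \code{omim_ar}, \code{segdup_overlap} and \code{roh_overlap} (list of
#'   named logicals, NA = unknown).
#' @export
deletion_events <- function(chrom = character(), start = integer(),
                            end = integer(), region_ids = list(),
                            sample_ids = list(), pattern = character(),
                            fdel_max = numeric()) {
  n <- length(chrom)
  if (n) stopifnot(all(end > start), all(lengths(region_ids) > 0))
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   size = as.integer(end) - as.integer(start),
                   pattern = as.character(pattern),
                   fdel_max = as.numeric(fdel_max),
                   stringsAsFactors = FALSE)
  df$region_ids <- lapply(region_ids, as.character)
  df$sample_ids <- lapply(sample_ids, as.character)
  if (n) df <- df[order(as.integer(df$chrom), df$start, df$end, df$pattern), ,
                  drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("deletion_events", "data.frame")
  df
}

#' @export
print.deletion_events <- function(x, ...) {
  cat(sprintf("deletion_events: %d event(s)\n", nrow(x)))
  if (nrow(x)) {
    show <- data.frame(chrom = x$chrom, start = x$start, end = x$end,
                       size = x$size,
                       n_regions = lengths(x$region_ids),
                       n_samples = lengths(x$sample_ids),
                       pattern = x$pattern, fdel_max = x$fdel_max)
    print(utils::head(show, 10))
    if (nrow(x) > 10) cat(sprintf("... and %d more\n", nrow(x) - 10))
  }
  invisible(x)
}

#' Merge contiguous region-level CN 0 calls into deletion events
#'
#' A single real deletion that spans several adjacent regions produces one
#' CN 0 call per region; this chains them back into one event. Within each
#' sample, called regions on the same chromosome are chained when they are
#' consecutive among the unmasked regions of the region set (no intervening
#' unmasked region escaped calling) and the genomic gap between them
#' (next start minus current end) is at most \code{max_gap}. Each chain
#' becomes one event whose span is the union of its member region intervals.
#' Events from different samples with identical spans (same chromosome,
#' start, end and pattern) are consolidated into one event listing every
#' supporting sample — this consolidation is what turns per-trio calls into
#' "distinct" deletions.
#'
#' @param calls data frame of region-level calls with a \code{region_id}
#'   column and a carrier column (\code{sample_id}, or \code{proband_id}
#'   for trio calls); an optional \code{pattern} column is carried through.
#' @param regions the [region_set] the calls refer to.
#' @param max_gap maximum genomic gap (bp) bridged between consecutive
#'   called regions (default 100000; gene regions are not tiling, so
#'   adjacent deleted genes within one CNV are separated by intergenic
#'   distance).
#' @param masked optional character vector (or named logical) of masked
#'   region ids, excluded from the "no intervening un-called region" test;
#'   defaults to none.
#' @param fdel optional \code{fdel_table}; when given, each event gets
#'   \code{fdel_max} = max fdel over its member regions.
#' @return A [deletion_events] data frame.
#' @export
merge_contiguous_calls <- function(calls, regions, max_gap = 100000L,
                                   masked = NULL, fdel = NULL) {
  sample_col <- if ("sample_id" %in% names(calls)) "sample_id" else "proband_id"
  if (!sample_col %in% names(calls))
    stop("calls need a 'sample_id' or 'proband_id' column")
  unknown <- setdiff(calls$region_id, regions$region_id)
  if (length(unknown))
    stop("unknown region id(s) in calls: ", paste(unknown, collapse = ", "))
  if (is.logical(masked)) masked <- names(masked)[masked]
  if (is.null(masked)) masked <- character()
  # rank of each region among unmasked regions, in region-set order
  unmasked <- !regions$region_id %in% masked
  pos <- rep(NA_integer_, nrow(regions))
  pos[unmasked] <- seq_len(sum(unmasked))
  names(pos) <- regions$region_id

  if (!nrow(calls)) return(deletion_events())
  if (!"pattern" %in% names(calls)) calls$pattern <- "cn0"
  calls <- calls[!calls$region_id %in% masked, , drop = FALSE]

  ridx <- match(calls$region_id, regions$region_id)
  ord <- order(calls[[sample_col]], calls$pattern, ridx)
  calls <- calls[ord, , drop = FALSE]
  ridx <- ridx[ord]

  key <- paste(calls[[sample_col]], calls$pattern, sep = "\r")
  chains_chrom <- character(); chains_start <- integer()
  chains_end <- integer(); chains_regions <- list()
  chains_sample <- character(); chains_pattern <- character()
  for (grp in split(seq_along(ridx), key)) {
    idx <- ridx[grp]  # sorted region row indices for one sample+pattern
    brk <- c(TRUE, vapply(seq_along(idx)[-1], function(i) {
      a <- idx[i - 1]; b <- idx[i]
      regions$chrom[a] != regions$chrom[b] ||
        pos[b] != pos[a] + 1L ||
        (regions$start[b] - regions$end[a]) > max_gap
    }, logical(1)))
    chain_id <- cumsum(brk)
    for (ch in split(idx, chain_id)) {
      chains_chrom <- c(chains_chrom, regions$chrom[ch[1]])
      chains_start <- c(chains_start, min(regions$start[ch]))
      chains_end <- c(chains_end, max(regions$end[ch]))
      chains_regions <- c(chains_regions, list(regions$region_id[ch]))
      chains_sample <- c(chains_sample, calls[[sample_col]][grp[1]])
      chains_pattern <- c(chains_pattern, calls$pattern[grp[1]])
    }
  }
  # consolidate identical spans across samples
  span_key <- paste(chains_chrom, chains_start, chains_end, chains_pattern)
  grp <- split(seq_along(span_key), span_key)
  fmax <- function(ids) {
    if (is.null(fdel)) return(NA_real_)
    v <- fdel$fdel[match(ids, fdel$region_id)]
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  }
  ev <- lapply(grp, function(g) {
    rids <- unique(unlist(chains_regions[g]))
    rids <- rids[order(match(rids, regions$region_id))]
    list(chrom = chains_chrom[g[1]], start = chains_start[g[1]],
         end = chains_end[g[1]], region_ids = rids,
         sample_ids = sort(unique(chains_sample[g])),
         pattern = chains_pattern[g[1]], fdel_max = fmax(rids))
  })
  ev <- unname(ev)
  deletion_events(
    chrom = vapply(ev, `[[`, "", "chrom"),
    start = vapply(ev, function(e) e$start, integer(1)),
    end = vapply(ev, function(e) e$end, integer(1)),
    region_ids = lapply(ev, `[[`, "region_ids"),
    sample_ids = lapply(ev, `[[`, "sample_ids"),
    pattern = vapply(ev, `[[`, "", "pattern"),
    fdel_max = vapply(ev, function(e) e$fdel_max, numeric(1)))
}

#' Filter deletion events by minimum size
#'
#' Retains events whose genomic span is at least \code{min_size} base pairs
#' (inclusive: an event of exactly \code{min_size} bp passes).
#'
#' @param events a [deletion_events] data frame.
#' @param min_size minimum size in bp (default 8000); must be positive.
#' @return The retained subset.
#' @export
apply_size_filter <- function(events, min_size = 8000L) {
  if (!is.numeric(min_size) || length(min_size) != 1 || min_size <= 0)
    stop("min_size must be a single positive number")
  out <- events[events$size >= min_size, , drop = FALSE]
  rownames(out) <- NULL
  out
}
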