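#' Annotation tables
#'
#' Bundles the three external annotation resources used to interpret
#' deletion events: per-gene OMIM flags (is the gene disease-associated, and
#' is the inheritance autosomal recessive), segmental-duplication intervals
#' (low-copy repeats that mediate recurrent CNV formation), and per-sample
#' runs of homozygosity (ROH; large runs indicate autozygosity by descent).
#' All intervals are 0-based half-open on autosome labels without a "chr"
#' prefix.
#'
#' @param gene_flags data frame with columns \code{gene_symbol},
#'   \code{omim_morbid}, \code{omim_ar} (logical).
#' @param segdup data frame with columns \code{chrom}, \code{start},
#'   \code{end}.
#' @param roh named list mapping sample id to a data frame with columns
#'   \code{chrom}, \code{start}, \code{end}; samples absent from the list
#'   have unknown ROH status.
#' @return An \code{annotation_tables} list.
#' @export
annotation_tables <- function(gene_flags = NULL, segdup = NULL, roh = list()) {
  if (is.null(gene_flags))
    gene_flags <- data.frame(gene_symbol = character(),
                             omim_morbid = logical(), omim_ar = logical(),
                             stringsAsFactors = FALSE)
  gene_flags$omim_morbid <- as.logical(gene_flags$omim_morbid)
  gene_flags$omim_ar <- as.logical(gene_flags$omim_ar)
  if (anyDuplicated(gene_flags$gene_symbol))
    stop("duplicate gene_symbol in gene_flags")
  check_iv <- function(df, what) {
    if (is.null(df))
      return(data.frame(chrom = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE))
    df <- as.data.frame(df)[c("chrom", "start", "end")]
    df$chrom <- normalize_chrom(as.character(df$chrom))
    df$start <- as.integer(df$start); df$end <- as.integer(df$end)
    if (any(df$end <= df$start)) stop(what, ": intervals need end > start")
    df
  }
  segdup <- check_iv(segdup, "segdup")
  roh <- lapply(roh, check_iv, what = "roh")
  structure(list(gene_flags = gene_flags, segdup = segdup, roh = roh),
            class = "annotation_tables")
}

#' Read annotation inputs
#'
#' \code{read_gene_flags} reads a TSV with header
#' \code{gene_symbol<TAB>omim_morbid<TAB>omim_ar} (flags as TRUE/FALSE or
#' 1/0). \code{read_segdup_bed} reads a 3+ column BED. \code{read_roh_bed}
#' reads a 4-column BED whose name column carries the sample id, returning
#' the per-sample interval list.
#'
#' @param path file path.
#' @name annotation_io
#' @export
read_gene_flags <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", NA, NA), quote = "")
  df$omim_morbid <- as.logical(df$omim_morbid)
  df$omim_ar <- as.logical(df$omim_ar)
  df
}

#' @rdname annotation_io
#' @export
read_segdup_bed <- function(path) {
  read_bed3(path)
}

#' @rdname annotation_io
#' @export
read_roh_bed <- function(path) {
  df <- read_bed3(path, n_extra = 1, extra_names = "sample_id")
  lapply(split(df[c("chrom", "start", "end")], df$sample_id),
         function(d) { rownames(d) <- NULL; d })
}

read_bed3 <- function(path, n_extra = 0, extra_names = character()) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^(track|browser|#)", lines)]
  cols <- c("chrom", "start", "end", extra_names)
  if (!length(lines)) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
    for (nm in extra_names) out[[nm]] <- character()
    return(out)
  }
  fields <- strsplit(lines, "\\s+")
  if (any(lengths(fields) < 3 + n_extra))
    stop("BED line ", which(lengths(fields) < 3 + n_extra)[1],
         ": fewer than ", 3 + n_extra, " columns in ", path)
  out <- data.frame(chrom = normalize_chrom(vapply(fields, `[[`, "", 1L)),
                    start = as.integer(vapply(fields, `[[`, "", 2L)),
                    end = as.integer(vapply(fields, `[[`, "", 3L)),
                    stringsAsFactors = FALSE)
  for (i in seq_along(extra_names))
    out[[extra_names[i]]] <- vapply(fields, `[[`, "", 3L + i)
  out
}

#' Annotate deletion events
#'
#' Adds to each event: the gene symbols of its member regions; whether any
#' member gene is OMIM-morbid and whether any carries an autosomal recessive
#' OMIM annotation; whether the event span intersects a segmental
#' duplication (half-open intersection of at least 1 bp — a mechanism flag
#' for recurrent CNVs); and, per supporting sample, whether the event lies
#' fully inside a run of homozygosity of at least \code{roh_min} bp
#' (autozygosity evidence; containment, not mere overlap, because a deletion
#' inherited identical-by-descent sits inside the surrounding homozygous
#' tract). Samples without ROH data get NA (unknown), never FALSE.
#'
#' @param events a [deletion_events] data frame.
#' @param annot an [annotation_tables] bundle.
#' @param regions the [region_set] (source of gene symbols).
#' @param roh_min minimum ROH run length in bp to count as autozygosity
#'   (default 2000000, the conventional large-ROH threshold).
#' @return The events with annotation columns filled: \code{genes} (list),
#'   \code{omim_morbid}, \code{omim_ar}, \code{segdup_overlap},
#'   \code{roh_overlap} (list of named logicals).
#' @export
annotate_events <- function(events, annot, regions, roh_min = 2000000L) {
  gf <- annot$gene_flags
  n <- nrow(events)
  genes <- vector("list", n)
  morbid <- logical(n); ar <- logical(n); segdup <- logical(n)
  roh <- vector("list", n)
  for (i in seq_len(n)) {
    g <- regions$gene_symbol[match(events$region_ids[[i]], regions$region_id)]
    g <- unique(g[!is.na(g)])
    genes[[i]] <- g
    flags <- gf[match(g, gf$gene_symbol), , drop = FALSE]
    morbid[i] <- isTRUE(any(flags$omim_morbid, na.rm = TRUE))
    ar[i] <- isTRUE(any(flags$omim_ar, na.rm = TRUE))
    sd <- annot$segdup
    segdup[i] <- any(sd$chrom == events$chrom[i] &
                       sd$start < events$end[i] & events$start[i] < sd$end)
    samp <- events$sample_ids[[i]]
    rv <- stats::setNames(rep(NA, length(samp)), samp)
    for (s in samp) {
      iv <- annot$roh[[s]]
      if (is.null(iv)) next  # unknown, stays NA
      big <- iv[iv$end - iv$start >= roh_min & iv$chrom == events$chrom[i], ,
                drop = FALSE]
      rv[s] <- any(big$start <= events$start[i] & events$end[i] <= big$end)
    }
    roh[[i]] <- rv
  }
  events$genes <- genes
  events$omim_morbid <- morbid
  events$omim_ar <- ar
  events$segdup_overlap <- segdup
  events$roh_overlap <- roh
  events
}

#' Morbid-gene enrichment across rarity and size strata
#'
#' Tabulates per-gene deletion records into a grid of fdel bins by size
#' bins and reports, per cell, the number of OMIM-morbid and non-morbid
#' genes and the morbid proportion. This is the summary used to justify the
#' rarity (< 0.5%) and size (>= 8 kb) filters: morbid-gene deletions
#' concentrate in the rare, large stratum.
#'
#' @param records data frame with columns \code{gene_symbol}, \code{fdel},
#'   \code{size}.
#' @param annot an [annotation_tables] bundle; genes absent from
#'   \code{gene_flags} count as non-morbid.
#' @param fdel_bins,size_bins strictly increasing numeric vectors of
#'   interior bin edges; values below the first edge fall in bin 1, values
#'   at or above the last edge in the final bin.
#' @return Data frame with one row per (fdel_bin, size_bin) cell:
#'   \code{fdel_bin}, \code{size_bin} (interval labels), \code{n_morbid},
#'   \code{n_nonmorbid}, \code{prop_morbid} (NA for empty cells).
#' @export
morbid_enrichment <- function(records, annot,
                              fdel_bins = c(0.001, 0.005, 0.02),
                              size_bins = c(8000, 50000, 250000)) {
  for (edges in list(fdel_bins, size_bins))
    if (length(edges) < 1 || is.unsorted(edges, strictly = TRUE))
      stop("bin edges must be non-empty and strictly increasing")
  bin_label <- function(edges) {
    lo <- c("-Inf", format(edges)); hi <- c(format(edges), "Inf")
    paste0("[", lo, ",", hi, ")")
  }
  fl <- bin_label(fdel_bins); sl <- bin_label(size_bins)
  if (!nrow(records)) {
    return(data.frame(fdel_bin = character(), size_bin = character(),
                      n_morbid = integer(), n_nonmorbid = integer(),
                      prop_morbid = numeric(), stringsAsFactors = FALSE))
  }
  fb <- findInterval(records$fdel, fdel_bins) + 1L
  sb <- findInterval(records$size, size_bins) + 1L
  gm <- annot$gene_flags$omim_morbid[
    match(records$gene_symbol, annot$gene_flags$gene_symbol)]
  gm[is.na(gm)] <- FALSE
  grid <- expand.grid(fdel_bin = seq_along(fl), size_bin = seq_along(sl))
  n_m <- integer(nrow(grid)); n_n <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    in_cell <- fb == grid$fdel_bin[i] & sb == grid$size_bin[i]
    n_m[i] <- sum(in_cell & gm)
    n_n[i] <- sum(in_cell & !gm)
  }
  tot <- n_m + n_n
  data.frame(fdel_bin = fl[grid$fdel_bin], size_bin = sl[grid$size_bin],
             n_morbid = n_m, n_nonmorbid = n_n,
             prop_morbid = ifelse(tot > 0, n_m / tot, NA_real_),
             stringsAsFactors = FALSE)
}
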