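#' Region sets
#'
#' A region set is the atomic coordinate system of the pipeline: an ordered
#' collection of autosomal genomic intervals (0-based, half-open), each with a
#' unique identifier and an optional gene symbol. Depth is measured, copy
#' number is called, and deletion events are built region by region.
#'
#' @param region_id character vector of unique identifiers.
#' @param chrom character vector of chromosome labels; only autosomes
#'   ("1".."22", with or without a leading "chr") are accepted.
#' @param start,end integer vectors of 0-based half-open coordinates,
#'   \code{end > start >= 0}.
#' @param gene_symbol optional character vector of gene symbols (NA allowed).
#' @return A \code{region_set}: a data frame with columns \code{region_id},
#'   \code{chrom}, \code{start}, \code{end}, \code{gene_symbol}, sorted by
#'   (chromosome as integer, start).
#' @examples
#' region_set(c("r1", "r2"), c("2", "1"), c(100L, 0L), c(200L, 50L))
#' @export
region_set <- function(region_id, chrom, start, end, gene_symbol = NULL) {
  n <- length(region_id)
  chrom <- normalize_chrom(as.character(chrom))
  start <- as.integer(round(as.numeric(start)))
  end <- as.integer(round(as.numeric(end)))
  if (is.null(gene_symbol)) gene_symbol <- rep(NA_character_, n)
  gene_symbol <- as.character(gene_symbol)
  stopifnot(length(chrom) == n, length(start) == n, length(end) == n,
            length(gene_symbol) == n)
  if (anyDuplicated(region_id))
    stop("duplicate region_id: ",
         paste(unique(region_id[duplicated(region_id)]), collapse = ", "))
  bad <- which(!chrom %in% as.character(1:22))
  if (length(bad))
    stop("non-autosomal chromosome in region_set: ",
         paste(unique(chrom[bad]), collapse = ", "))
  bad <- which(is.na(start) | is.na(end) | start < 0 | end <= start)
  if (length(bad))
    stop("invalid coordinates (need 0 <= start < end) at rows: ",
         paste(bad, collapse = ", "))
  df <- data.frame(region_id = as.character(region_id), chrom = chrom,
                   start = start, end = end, gene_symbol = gene_symbol,
                   stringsAsFactors = FALSE)
  df <- df[order(as.integer(df$chrom), df$start, df$end, df$region_id), ,
           drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("region_set", "data.frame")
  df
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region_set with %d autosomal regions on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat(sprintf("... and %d more\n", nrow(x) - 10))
  invisible(x)
}

# strip a leading "chr" so both GRCh38 dialects are accepted
normalize_chrom <- function(chrom) sub("^chr", "", chrom)

#' Read a region definition table (BED or TSV)
#'
#' Reads the interval table that defines the unit regions of analysis.
#' Non-autosomal records (chrX, chrY, contigs, ...) are dropped with a
#' warning reporting how many were removed.
#'
#' @param path path to the file.
#' @param format \code{"auto"} (by extension), \code{"bed"}
#'   (chrom, start, end and optional name column; the name doubles as both
#'   region id and gene symbol) or \code{"tsv"} (header with columns
#'   \code{region_id}, \code{chrom}, \code{start}, \code{end} and optional
#'   \code{gene_symbol}).
#' @return A [region_set] sorted by (chromosome, start).
#' @export
read_region_table <- function(path, format = c("auto", "bed", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "tsv"
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "bed") {
    lines <- lines[!grepl("^(track|browser|#)", lines)]
    if (!length(lines))
      return(region_set(character(), character(), integer(), integer()))
    fields <- strsplit(lines, "\\s+")
    nf <- lengths(fields)
    if (any(nf < 3))
      stop("BED line ", which(nf < 3)[1], ": fewer than 3 columns")
    chrom <- vapply(fields, `[[`, "", 1L)
    start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
    end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
    name <- vapply(fields, function(f) if (length(f) >= 4) f[[4]] else NA_character_, "")
    df <- data.frame(region_id = ifelse(is.na(name),
                                        paste0(chrom, ":", start, "-", end),
                                        name),
                     chrom = chrom, start = start, end = end,
                     gene_symbol = name, stringsAsFactors = FALSE)
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = "character", quote = "")
    need <- c("region_id", "chrom", "start", "end")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("TSV region table missing column(s): ", paste(miss, collapse = ", "))
    if (!"gene_symbol" %in% names(df)) df$gene_symbol <- NA_character_
    df <- df[c(need, "gene_symbol")]
    df$start <- suppressWarnings(as.numeric(df$start))
    df$end <- suppressWarnings(as.numeric(df$end))
  }
  bad <- which(is.na(df$start) | is.na(df$end) | df$start < 0 | df$end <= df$start)
  if (length(bad))
    stop("malformed coordinates at data line(s): ", paste(bad, collapse = ", "),
         " of ", path)
  df$chrom <- normalize_chrom(df$chrom)
  drop <- !df$chrom %in% as.character(1:22)
  if (any(drop)) {
    warning(sum(drop), " non-autosomal record(s) dropped from ", path)
    df <- df[!drop, , drop = FALSE]
  }
  region_set(df$region_id, df$chrom, df$start, df$end, df$gene_symbol)
}

#' Write a region set as a TSV region table
#'
#' @param regions a [region_set].
#' @param path output path.
#' @export
write_region_table <- function(regions, path) {
  utils::write.table(as.data.frame(regions), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
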