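#' Per-base coverage sources
#'
#' The primary depth input contract is per-base coverage for one sample: a
#' named list mapping chromosome label to a numeric vector, where element
#' \code{i} is the read depth at 0-based position \code{i - 1}. Positions
#' beyond the stored vector read as depth 0, so sparse or truncated coverage
#' is valid. [read_per_base_coverage()] builds such a source from the
#' three-column text output of a standard depth utility
#' (\code{chrom<TAB>pos<TAB>depth}, 1-based positions, e.g. `samtools depth`).
#'
#' @param x named list of non-negative numeric vectors keyed by chromosome.
#' @return A \code{coverage_source}.
#' @export
coverage_source <- function(x) {
  stopifnot(is.list(x), !is.null(names(x)), all(nzchar(names(x))))
  names(x) <- normalize_chrom(names(x))
  for (chr in names(x)) {
    v <- as.numeric(x[[chr]])
    if (any(!is.finite(v)) || any(v < 0))
      stop("coverage for chromosome ", chr, " must be finite and >= 0")
    x[[chr]] <- v
  }
  structure(x, class = "coverage_source")
}

#' @rdname coverage_source
#' @param path path to a per-base depth TSV (chrom, 1-based position, depth).
#' @export
read_per_base_coverage <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "pos", "depth"),
                          colClasses = c("character", "integer", "numeric"))
  df$chrom <- normalize_chrom(df$chrom)
  out <- lapply(split(df, df$chrom), function(d) {
    v <- numeric(max(d$pos))
    v[d$pos] <- d$depth
    v
  })
  coverage_source(out)
}

#' Mean per-base depth of one region
#'
#' The pipeline's primary signal: the arithmetic mean of per-base read depth
#' over a region's half-open interval. Uncovered bases contribute 0 and the
#' denominator is always the region length, so a deleted region yields a
#' depressed mean rather than a missing value.
#'
#' @param coverage a [coverage_source] for one sample.
#' @param region one-row slice of a [region_set] (or any list with
#'   \code{chrom}, \code{start}, \code{end}).
#' @return Non-negative scalar mean depth.
#' @export
mean_region_depth <- function(coverage, region) {
  chrom <- normalize_chrom(as.character(region$chrom))
  if (!chrom %in% names(coverage))
    stop("chromosome ", chrom, " absent from coverage source")
  start <- as.integer(region$start)
  end <- as.integer(region$end)
  stopifnot(length(chrom) == 1L, end > start, start >= 0)
  v <- coverage[[chrom]]
  # 0-based [start, end) maps to 1-based indices start+1 .. end
  idx <- seq.int(start + 1L, end)
  idx <- idx[idx <= length(v)]
  sum(v[idx]) / (end - start)
}

#' Build a samples-by-regions mean-depth matrix
#'
#' @param samples named list of [coverage_source] objects, one per sample;
#'   names are the sample ids.
#' @param regions a [region_set].
#' @return Numeric matrix, samples in rows (rownames = sample ids), regions
#'   in columns (colnames = region ids, in region-set order).
#' @export
build_depth_matrix <- function(samples, regions) {
  if (is.null(names(samples)) || any(!nzchar(names(samples))))
    stop("samples must be a named list of coverage sources")
  if (anyDuplicated(names(samples)))
    stop("duplicate sample_id: ",
         paste(unique(names(samples)[duplicated(names(samples))]), collapse = ", "))
  m <- matrix(0, nrow = length(samples), ncol = nrow(regions),
              dimnames = list(names(samples), regions$region_id))
  for (s in names(samples)) {
    cov <- samples[[s]]
    m[s, ] <- vapply(seq_len(nrow(regions)), function(i)
      mean_region_depth(cov, regions[i, ]), numeric(1))
  }
  m
}

#' Read / write a depth (or copy-number) matrix TSV
#'
#' On disk the matrix is stored regions-by-samples: first column
#' \code{region_id}, one further column per sample. In memory the pipeline
#' works samples-by-regions, so these functions transpose.
#'
#' @param path file path.
#' @return For the reader, a numeric matrix with samples in rows and regions
#'   in columns.
#' @export
read_depth_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, quote = "")
  if (names(df)[1] != "region_id")
    stop("depth matrix TSV must have first column 'region_id'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$region_id
  storage.mode(m) <- "double"
  if (any(!is.finite(m)) || any(m < 0))
    stop("depth matrix contains negative or non-finite values")
  t(m)
}

#' @rdname read_depth_matrix
#' @param depths samples-by-regions numeric matrix.
#' @export
write_depth_matrix <- function(depths, path) {
  df <- data.frame(region_id = colnames(depths), t(depths),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
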