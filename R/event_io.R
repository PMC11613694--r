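#' Write / read a deletion event table
#'
#' The TSV report has one row per event with columns \code{chrom},
#' \code{start}, \code{end}, \code{size}, \code{region_ids}, \code{pattern},
#' \code{fdel}, \code{genes}, \code{omim_morbid}, \code{omim_ar},
#' \code{segdup_overlap}, \code{roh_overlap}, \code{sample_ids}, plus a
#' human-readable \code{coord_1based} column (1-based inclusive). Coordinates
#' are 0-based half-open throughout. Multi-valued fields are comma-joined;
#' \code{roh_overlap} is encoded per supporting sample as
#' \code{sample=TRUE|FALSE|NA}; "." marks a field on an event that was never
#' annotated. \code{read_event_table} on a TSV written by
#' \code{write_event_table} reconstructs field-identical events. The BED
#' format writes chrom, start, end, a name column with the supporting
#' samples, and the size as score.
#'
#' @param events a [deletion_events] data frame.
#' @param path output path.
#' @param format \code{"tsv"} (full, round-trippable) or \code{"bed"}.
#' @export
write_event_table <- function(events, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  join <- function(xs) vapply(xs, function(v)
    if (length(v)) paste(v, collapse = ",") else ".", "")
  if (format == "bed") {
    lines <- if (nrow(events))
      paste(events$chrom, events$start, events$end,
            join(events$sample_ids), events$size, sep = "\t")
    else character()
    writeLines(lines, path)
    return(invisible(path))
  }
  n <- nrow(events)
  annotated <- "genes" %in% names(events)
  num <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  roh_enc <- function(rv) {
    if (!length(rv)) return(".")
    paste(names(rv), ifelse(is.na(rv), "NA", as.character(rv)),
          sep = "=", collapse = ",")
  }
  df <- data.frame(
    chrom = events$chrom, start = events$start, end = events$end,
    size = events$size,
    region_ids = join(events$region_ids),
    pattern = events$pattern,
    fdel = num(events$fdel_max),
    genes = if (annotated) join(events$genes) else rep(".", n),
    omim_morbid = if (annotated) as.character(events$omim_morbid) else rep(".", n),
    omim_ar = if (annotated) as.character(events$omim_ar) else rep(".", n),
    segdup_overlap = if (annotated) as.character(events$segdup_overlap) else rep(".", n),
    roh_overlap = if (annotated) vapply(events$roh_overlap, roh_enc, "")
                  else rep(".", n),
    sample_ids = join(events$sample_ids),
    coord_1based = if (n)
      paste0(events$chrom, ":", events$start + 1L, "-", events$end)
    else character(),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  split_field <- function(x) lapply(x, function(v)
    if (v == ".") character() else strsplit(v, ",", fixed = TRUE)[[1]])
  ev <- deletion_events(
    chrom = df$chrom, start = as.integer(df$start), end = as.integer(df$end),
    region_ids = split_field(df$region_ids),
    sample_ids = split_field(df$sample_ids),
    pattern = df$pattern,
    fdel_max = suppressWarnings(as.numeric(ifelse(df$fdel == "NA", NA, df$fdel))))
  if (nrow(df) && any(df$genes != "." | df$omim_morbid != ".")) {
    ev$genes <- split_field(df$genes)
    ev$omim_morbid <- as.logical(df$omim_morbid)
    ev$omim_ar <- as.logical(df$omim_ar)
    ev$segdup_overlap <- as.logical(df$segdup_overlap)
    ev$roh_overlap <- lapply(df$roh_overlap, function(v) {
      if (v == ".") return(stats::setNames(logical(), character()))
      parts <- strsplit(strsplit(v, ",", fixed = TRUE)[[1]], "=", fixed = TRUE)
      stats::setNames(as.logical(vapply(parts, `[[`, "", 2L)),
                      vapply(parts, `[[`, "", 1L))
    })
  }
  ev
}
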