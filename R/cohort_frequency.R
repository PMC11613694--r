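#' Heterozygous-deletion frequency (fdel) in a control cohort
#'
#' For each unmasked region, counts the control individuals carrying a
#' heterozygous deletion (copy number exactly 1) and reports
#' fdel = n_het / n_controls. Homozygous control deletions (CN 0) are
#' tallied separately as \code{n_hom} and are deliberately not folded into
#' fdel: fdel is defined as the frequency of heterozygous deletion carriers.
#'
#' @param cn_controls a \code{cn_matrix} for the control cohort.
#' @return An \code{fdel_table}: data frame with columns \code{region_id},
#'   \code{fdel}, \code{n_het}, \code{n_hom}, \code{n_controls}; masked
#'   regions yield no row.
#' @export
heterozygous_deletion_frequency <- function(cn_controls) {
  if (nrow(cn_controls) < 1) stop("control cohort is empty")
  mask <- cn_mask(cn_controls)
  keep <- names(mask)[!mask]
  sub <- cn_controls[, keep, drop = FALSE]
  n <- nrow(sub)
  n_het <- colSums(sub == 1L, na.rm = TRUE)
  n_hom <- colSums(sub == 0L, na.rm = TRUE)
  out <- data.frame(region_id = keep,
                    fdel = unname(n_het) / n,
                    n_het = as.integer(unname(n_het)),
                    n_hom = as.integer(unname(n_hom)),
                    n_controls = n,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("fdel_table", "data.frame")
  out
}

#' Filter calls by control-cohort deletion rarity
#'
#' Retains calls whose region has fdel strictly below \code{max_fdel}
#' (the discovery filter is "frequency < 0.5%", so a region at exactly the
#' threshold is removed). A call at a region absent from the fdel table is
#' dropped with a warning: rarity cannot be asserted without control data,
#' so unknown frequency fails closed.
#'
#' @param calls data frame of trio or singleton calls carrying a
#'   \code{region_id} column.
#' @param fdel an \code{fdel_table} from [heterozygous_deletion_frequency()].
#' @param max_fdel strict upper bound on fdel, in (0, 1] (default 0.005).
#' @return The retained subset of \code{calls}.
#' @export
apply_frequency_filter <- function(calls, fdel, max_fdel = 0.005) {
  if (!is.numeric(max_fdel) || length(max_fdel) != 1 ||
      max_fdel <= 0 || max_fdel > 1)
    stop("max_fdel must be a single value in (0, 1]")
  if (!nrow(calls)) return(calls)
  f <- fdel$fdel[match(calls$region_id, fdel$region_id)]
  unknown <- is.na(f)
  if (any(unknown))
    warning(sum(unknown), " call(s) at region(s) with unknown fdel dropped: ",
            paste(unique(calls$region_id[unknown]), collapse = ", "))
  out <- calls[!unknown & f < max_fdel, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write an fdel table TSV
#'
#' @param path file path.
#' @export
read_fdel_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "numeric", "integer",
                                         "integer", "integer"))
  class(df) <- c("fdel_table", "data.frame")
  df
}

#' @rdname read_fdel_table
#' @param fdel an \code{fdel_table}.
#' @export
write_fdel_table <- function(fdel, path) {
  utils::write.table(as.data.frame(fdel), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
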