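#' Inheritance-pattern detectors over a copy-number matrix
#'
#' The discovery genotype pattern is CN 0-1-1: proband homozygous deletion
#' (copy number 0) with a heterozygous deletion (copy number 1) in each
#' parent, i.e. an inheritance pattern compatible with autosomal recessive
#' disease. [find_inherited_biallelic()] returns exactly those (trio, region)
#' pairs. [flag_de_novo_candidates()] flags probands at CN 0 where exactly
#' one parent cannot have transmitted a deleted allele (CN >= 2) while the
#' other can (CN <= 1) — the single-de-novo pattern; probands at CN 0 with
#' both parents at CN >= 2 would require two independent de novo events and
#' are reported in a diagnostics attribute, not called.
#'
#' @param cn a \code{cn_matrix} from [call_copy_numbers()] (samples in rows,
#'   regions in columns, in region-set order).
#' @param trios a [trio_set].
#' @return Data frame of trio calls with columns \code{proband_id},
#'   \code{father_id}, \code{mother_id}, \code{region_id},
#'   \code{proband_cn}, \code{father_cn}, \code{mother_cn}, \code{pattern},
#'   sorted by region order (chromosome, start) then proband id. For
#'   [flag_de_novo_candidates()] the double-de-novo diagnostics are attached
#'   as \code{attr(, "double_de_novo")}.
#' @export
find_inherited_biallelic <- function(cn, trios) {
  scan_trios(cn, trios, function(p, f, m) p == 0L & f == 1L & m == 1L,
             "inherited_biallelic")
}

#' @rdname find_inherited_biallelic
#' @export
flag_de_novo_candidates <- function(cn, trios) {
  out <- scan_trios(cn, trios, function(p, f, m)
    p == 0L & ((f >= 2L & m <= 1L) | (m >= 2L & f <= 1L)),
    "de_novo_candidate")
  diag <- scan_trios(cn, trios, function(p, f, m) p == 0L & f >= 2L & m >= 2L,
                     "double_de_novo")
  attr(out, "double_de_novo") <- diag
  out
}

scan_trios <- function(cn, trios, predicate, pattern) {
  tr <- trios$trios
  members <- unique(unlist(tr[c("proband_id", "father_id", "mother_id")]))
  missing <- setdiff(members, rownames(cn))
  if (length(missing))
    stop("trio member(s) missing from CN matrix: ",
         paste(missing, collapse = ", "))
  empty <- data.frame(proband_id = character(), father_id = character(),
                      mother_id = character(), region_id = character(),
                      proband_cn = integer(), father_cn = integer(),
                      mother_cn = integer(), pattern = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(tr)) return(empty)
  mask <- cn_mask(cn)
  p <- cn[tr$proband_id, , drop = FALSE]
  f <- cn[tr$father_id, , drop = FALSE]
  m <- cn[tr$mother_id, , drop = FALSE]
  hit <- predicate(p, f, m)
  hit[is.na(hit)] <- FALSE
  hit[, mask] <- FALSE
  idx <- which(hit, arr.ind = TRUE)
  if (!nrow(idx)) return(empty)
  out <- data.frame(
    proband_id = tr$proband_id[idx[, 1]],
    father_id = tr$father_id[idx[, 1]],
    mother_id = tr$mother_id[idx[, 1]],
    region_id = colnames(cn)[idx[, 2]],
    proband_cn = p[idx], father_cn = f[idx], mother_cn = m[idx],
    pattern = pattern, stringsAsFactors = FALSE)
  # column order of cn follows the region set, i.e. (chrom, start)
  out <- out[order(match(out$region_id, colnames(cn)), out$proband_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Targeted screen of singleton probands at discovered loci
#'
#' Second phase of the two-phase design: loci discovered (and
#' frequency-filtered) in the trio cohort are re-queried in probands lacking
#' parental data. No frequency filter is re-applied; the targets already
#' passed it.
#'
#' @param cn a \code{cn_matrix} containing the singleton samples.
#' @param singletons character vector of singleton proband ids.
#' @param targets character vector of target region ids (must exist in the
#'   matrix).
#' @return Data frame with columns \code{sample_id}, \code{region_id},
#'   \code{cn} (always 0 for reported hits), ordered by region then sample.
#' @export
targeted_singleton_screen <- function(cn, singletons, targets) {
  unknown <- setdiff(targets, colnames(cn))
  if (length(unknown))
    stop("unknown target region_id(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(singletons, rownames(cn))
  if (length(missing))
    stop("singleton sample(s) missing from CN matrix: ",
         paste(missing, collapse = ", "))
  empty <- data.frame(sample_id = character(), region_id = character(),
                      cn = integer(), stringsAsFactors = FALSE)
  if (!length(targets) || !length(singletons)) return(empty)
  mask <- cn_mask(cn)
  targets <- targets[!mask[targets]]
  if (!length(targets)) return(empty)
  sub <- cn[singletons, targets, drop = FALSE]
  hit <- !is.na(sub) & sub == 0L
  idx <- which(hit, arr.ind = TRUE)
  if (!nrow(idx)) return(empty)
  out <- data.frame(sample_id = singletons[idx[, 1]],
                    region_id = targets[idx[, 2]],
                    cn = 0L, stringsAsFactors = FALSE)
  out <- out[order(match(out$region_id, colnames(cn)), out$sample_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
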