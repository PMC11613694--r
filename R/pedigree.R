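#' Trio sets
#'
#' Pedigrees are reduced to the two sample groupings the pipeline uses:
#' complete parent-child trios (proband plus both sequenced parents) and
#' singleton probands (at least one parent without data), which are screened
#' only at loci already discovered in the trios.
#'
#' @param trios data frame with columns \code{proband_id}, \code{father_id},
#'   \code{mother_id} and optionally \code{family_id}.
#' @param singletons character vector of singleton proband ids.
#' @return A \code{trio_set}: list with elements \code{trios} (data frame)
#'   and \code{singletons} (character vector).
#' @export
trio_set <- function(trios, singletons = character()) {
  if (is.null(trios) || nrow(as.data.frame(trios)) == 0) {
    trios <- data.frame(family_id = character(), proband_id = character(),
                        father_id = character(), mother_id = character(),
                        stringsAsFactors = FALSE)
  } else {
    trios <- as.data.frame(trios, stringsAsFactors = FALSE)
    if (!"family_id" %in% names(trios)) trios$family_id <- trios$proband_id
    trios <- trios[c("family_id", "proband_id", "father_id", "mother_id")]
  }
  with_ids <- function(ids, what) {
    if (any(!nzchar(ids) | is.na(ids))) stop("empty ", what, " identifier")
    ids
  }
  with_ids(trios$proband_id, "proband")
  with_ids(trios$father_id, "father")
  with_ids(trios$mother_id, "mother")
  bad <- trios$father_id == trios$mother_id |
    trios$proband_id == trios$father_id | trios$proband_id == trios$mother_id
  if (any(bad))
    stop("trio members not distinct for proband(s): ",
         paste(trios$proband_id[bad], collapse = ", "))
  if (anyDuplicated(trios$proband_id))
    stop("sample appears as proband in two trios: ",
         paste(unique(trios$proband_id[duplicated(trios$proband_id)]),
               collapse = ", "))
  out <- list(trios = trios, singletons = as.character(singletons))
  class(out) <- "trio_set"
  out
}

#' @export
print.trio_set <- function(x, ...) {
  cat(sprintf("trio_set: %d complete trio(s), %d singleton proband(s)\n",
              nrow(x$trios), length(x$singletons)))
  invisible(x)
}

#' Read a PED pedigree file into a trio set
#'
#' The PED dialect is six whitespace-delimited columns: family id, individual
#' id, father id, mother id, sex, phenotype, with \code{"0"} marking a missing
#' parent. An individual becomes a trio proband when both named parents have
#' their own row in the file; an individual with one or both parents missing
#' (or absent from the file) who is not themselves a parent of a trio is
#' placed on the singleton list.
#'
#' @param path path to the PED file.
#' @return A [trio_set].
#' @export
read_pedigree <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (!length(lines)) return(trio_set(NULL))
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 4))
    stop("PED line ", which(nf < 4)[1], ": fewer than 4 columns")
  ped <- data.frame(
    family_id = vapply(fields, `[[`, "", 1L),
    individual_id = vapply(fields, `[[`, "", 2L),
    father_id = vapply(fields, `[[`, "", 3L),
    mother_id = vapply(fields, `[[`, "", 4L),
    stringsAsFactors = FALSE)
  if (anyDuplicated(ped$individual_id))
    stop("duplicate individual_id in pedigree: ",
         paste(unique(ped$individual_id[duplicated(ped$individual_id)]),
               collapse = ", "))
  named <- ped$father_id != "0" & ped$mother_id != "0"
  if (any(named & ped$father_id == ped$mother_id))
    stop("father_id equals mother_id for individual(s): ",
         paste(ped$individual_id[named & ped$father_id == ped$mother_id],
               collapse = ", "))
  complete <- named & ped$father_id %in% ped$individual_id &
    ped$mother_id %in% ped$individual_id
  trios <- ped[complete, c("family_id", "individual_id", "father_id",
                           "mother_id"), drop = FALSE]
  names(trios)[2] <- "proband_id"
  parents <- unique(c(trios$father_id, trios$mother_id))
  singles <- ped$individual_id[!complete & !ped$individual_id %in% parents]
  trio_set(trios, singles)
}

#' Write a trio set as a PED file
#'
#' Parents are emitted as founder rows; sex and phenotype are written as
#' missing (father sex 1, mother sex 2 for trio parents).
#'
#' @param trioset a [trio_set].
#' @param path output path.
#' @export
write_pedigree <- function(trioset, path) {
  tr <- trioset$trios
  rows <- character(0)
  if (nrow(tr)) {
    rows <- c(
      paste(tr$family_id, tr$father_id, 0, 0, 1, 0),
      paste(tr$family_id, tr$mother_id, 0, 0, 2, 0),
      paste(tr$family_id, tr$proband_id, tr$father_id, tr$mother_id, 0, 0))
  }
  if (length(trioset$singletons))
    rows <- c(rows, paste(trioset$singletons, trioset$singletons, 0, 0, 0, 0))
  writeLines(rows, path)
  invisible(path)
}
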