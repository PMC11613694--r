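#' Pipeline configuration
#'
#' Bundles inputs and thresholds for the full autosomal-recessive deletion
#' discovery workflow. Inputs may be given as in-memory objects or as file
#' paths (region table TSV/BED, PED pedigree, depth matrix TSVs).
#'
#' @param regions a [region_set] or path.
#' @param pedigree a [trio_set] or PED path; trio members must be present
#'   in the case depth matrix.
#' @param case_depth samples-by-regions depth matrix (or TSV path) for the
#'   rare-disease cohort (probands and parents).
#' @param control_depth depth matrix (or TSV path) for the control cohort
#'   used to estimate fdel.
#' @param annotations optional [annotation_tables].
#' @param max_fdel control-cohort rarity threshold, strict (default 0.005).
#' @param min_size minimum merged-event size in bp, inclusive
#'   (default 8000).
#' @param bins,cn_max copy-number bin edges and cap, see
#'   [call_copy_numbers()].
#' @param min_region_median region masking threshold, see
#'   [normalize_depth_matrix()].
#' @param max_gap merge gap in bp, see [merge_contiguous_calls()].
#' @param roh_min autozygosity run-length threshold in bp, see
#'   [annotate_events()].
#' @param out_dir optional output directory for the report files.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(regions, pedigree, case_depth, control_depth,
                            annotations = NULL, max_fdel = 0.005,
                            min_size = 8000L, bins = NULL, cn_max = 4L,
                            min_region_median = 0.1, max_gap = 100000L,
                            roh_min = 2000000L, out_dir = NULL) {
  if (max_fdel <= 0 || max_fdel > 1) stop("max_fdel must be in (0, 1]")
  if (min_size <= 0) stop("min_size must be positive")
  if (max_gap < 0) stop("max_gap must be non-negative")
  structure(list(regions = regions, pedigree = pedigree,
                 case_depth = case_depth, control_depth = control_depth,
                 annotations = annotations, max_fdel = max_fdel,
                 min_size = min_size, bins = bins, cn_max = cn_max,
                 min_region_median = min_region_median, max_gap = max_gap,
                 roh_min = roh_min, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the autosomal-recessive deletion discovery pipeline
#'
#' Executes the full discovery workflow over a trio cohort:
#' normalize case and control depth matrices, call copy numbers, estimate
#' per-region heterozygous-deletion frequency (fdel) in the controls, find
#' trio CN 0-1-1 calls, filter them by rarity (fdel < max_fdel, per
#' region), merge contiguous surviving calls into distinct events, filter
#' by size (>= min_size), and annotate. The filter order
#' (frequency, merge, size) follows from the quantities' granularity: fdel
#' is per region, size is per merged event. De novo candidate loci
#' (proband CN 0 with a non-carrier parent) are reported alongside, and the
#' final events' region ids are emitted as the target list for the
#' follow-up singleton screen.
#'
#' @param config a [pipeline_config].
#' @return List with \code{events} (annotated [deletion_events]),
#'   \code{fdel_table}, \code{trio_calls} (raw CN 0-1-1 calls),
#'   \code{de_novo} (candidate calls), \code{target_loci} (region ids of
#'   passing events), \code{log} (data frame of per-stage in/out counts),
#'   \code{cn_case} and \code{cn_controls}. With \code{out_dir} set, also
#'   writes \code{events.tsv}, \code{events.bed}, \code{fdel.tsv},
#'   \code{de_novo.tsv}, \code{target_loci.txt} and \code{run_log.tsv}.
#' @export
run_ar_discovery <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  regions <- stage("load_regions",
    if (is.character(config$regions)) read_region_table(config$regions)
    else config$regions)
  pedigree <- stage("load_pedigree",
    if (is.character(config$pedigree)) read_pedigree(config$pedigree)
    else config$pedigree)
  case_depth <- stage("load_case_depth",
    if (is.character(config$case_depth)) read_depth_matrix(config$case_depth)
    else config$case_depth)
  control_depth <- stage("load_control_depth",
    if (is.character(config$control_depth))
      read_depth_matrix(config$control_depth)
    else config$control_depth)
  members <- unique(unlist(pedigree$trios[c("proband_id", "father_id",
                                            "mother_id")]))
  missing <- setdiff(members, rownames(case_depth))
  if (length(missing))
    stop("pipeline stage 'check_inputs' failed: pedigree sample(s) absent ",
         "from case depth matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)

  log <- data.frame(stage = character(), n_in = integer(), n_out = integer(),
                    stringsAsFactors = FALSE)
  note <- function(stg, n_in, n_out)
    log <<- rbind(log, data.frame(stage = stg, n_in = n_in, n_out = n_out))

  cn_case <- stage("call_case", call_copy_numbers(
    normalize_depth_matrix(case_depth,
                           min_region_median = config$min_region_median),
    bins = config$bins, cn_max = config$cn_max))
  cn_controls <- stage("call_controls", call_copy_numbers(
    normalize_depth_matrix(control_depth,
                           min_region_median = config$min_region_median),
    bins = config$bins, cn_max = config$cn_max))
  fdel <- stage("fdel", heterozygous_deletion_frequency(cn_controls))
  trio_calls <- stage("trio_0_1_1",
                      find_inherited_biallelic(cn_case, pedigree))
  de_novo <- stage("de_novo", flag_de_novo_candidates(cn_case, pedigree))
  note("trio_0_1_1", nrow(pedigree$trios) * sum(!cn_mask(cn_case)),
       nrow(trio_calls))
  rare <- stage("frequency_filter",
                apply_frequency_filter(trio_calls, fdel, config$max_fdel))
  note("frequency_filter", nrow(trio_calls), nrow(rare))
  events <- stage("merge", merge_contiguous_calls(
    rare, regions, max_gap = config$max_gap,
    masked = cn_mask(cn_case), fdel = fdel))
  note("merge", nrow(rare), nrow(events))
  events <- {
    n_in <- nrow(events)
    out <- stage("size_filter", apply_size_filter(events, config$min_size))
    note("size_filter", n_in, nrow(out))
    out
  }
  if (!is.null(config$annotations))
    events <- stage("annotate", annotate_events(events, config$annotations,
                                                regions, config$roh_min))
  target_loci <- as.character(unique(unlist(events$region_ids)))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(config$out_dir, f)
    write_event_table(events, p("events.tsv"), "tsv")
    write_event_table(events, p("events.bed"), "bed")
    write_fdel_table(fdel, p("fdel.tsv"))
    utils::write.table(de_novo, p("de_novo.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeLines(target_loci, p("target_loci.txt"))
    utils::write.table(log, p("run_log.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(events = events, fdel_table = fdel, trio_calls = trio_calls,
       de_novo = de_novo, target_loci = target_loci, log = log,
       cn_case = cn_case, cn_controls = cn_controls)
}
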