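#' Deterministic synthetic region sets
#'
#' Lays out equally sized, equally spaced gene regions across the 22
#' autosomes (round-robin chromosome assignment, coordinates restarting per
#' chromosome). Defaults approximate a gene-level region table: 20 kb
#' regions separated by 30 kb of intergenic sequence, so a deletion spanning
#' k contiguous regions has a span of roughly 50k - 30 kb.
#'
#' @param n_regions number of regions.
#' @param region_length region length in bp (default 20000).
#' @param spacing intergenic gap in bp (default 30000).
#' @param n_chrom number of chromosomes to spread over (default
#'   \code{min(22, n_regions)}).
#' @return A [region_set] with ids \code{"R00001"}, ... and gene symbols
#'   \code{"GENE00001"}, ...
#' @export
sim_regions <- function(n_regions, region_length = 20000L, spacing = 30000L,
                        n_chrom = NULL) {
  if (is.null(n_chrom)) n_chrom <- min(22L, n_regions)
  stopifnot(n_regions >= 1, region_length >= 1, spacing >= 0,
            n_chrom >= 1, n_chrom <= 22)
  i <- seq_len(n_regions)
  chrom <- as.character(((i - 1L) %% n_chrom) + 1L)
  slot <- (i - 1L) %/% n_chrom  # position within the chromosome
  start <- 1000000L + slot * (region_length + spacing)
  region_set(sprintf("R%05d", i), chrom, start, start + region_length,
             sprintf("GENE%05d", i))
}

#' Simulation configuration
#'
#' The stated world of the synthetic cohorts. Founder genotypes at each
#' spiked deletion follow Hardy-Weinberg at the event's allele frequency;
#' trio children inherit one allele from each parent uniformly at random.
#' The expected mean depth of sample s at region r is
#' \code{mean_depth * g_s * e_r * CN/2} with lognormal sample and region
#' effects g and e; a homozygously deleted cell receives a small background
#' floor (default 1% of its expected diploid depth) standing in for
#' mismapped reads at low-copy repeats. Observed depth is produced by
#' drawing the region's read count (expected depth times region length over
#' read length) from the chosen noise model and converting back to mean
#' depth, so longer regions have tighter means, as in real data.
#'
#' @param n_controls,n_trios cohort sizes.
#' @param regions a [region_set], or NULL to auto-generate
#'   \code{n_regions} via [sim_regions()].
#' @param n_regions used when \code{regions} is NULL (default 100).
#' @param spiked_events list of \code{list(region_ids = <contiguous region
#'   ids>, p = <deletion allele frequency in [0, 0.5)>)}.
#' @param mean_depth expected diploid mean depth, reads (default 30).
#' @param noise \code{"none"}, \code{"poisson"} or \code{"negbin"}.
#' @param dispersion negative-binomial size parameter for the per-region
#'   read count (default 400, i.e. about 5% coefficient of variation of a
#'   region's mean depth — typical of WGS region-level depth after
#'   normalization).
#' @param read_length read length used to convert depth to counts
#'   (default 150).
#' @param region_effect_sd,sample_effect_sd lognormal sigma of the
#'   multiplicative region and sample effects (defaults 0.3 and 0.1).
#' @param background_floor_frac depth floor at CN 0 cells as a fraction of
#'   the cell's expected diploid depth (default 0.01).
#' @param de_novo_rate probability that a trio child loses one extra copy
#'   at a spiked event independent of parental genotypes (default 0).
#' @param force_parent_het if TRUE, both parents of every trio are set to
#'   exactly one deleted allele at every spiked event (Mendelian
#'   segregation testing).
#' @param seed integer seed; mandatory for reproducibility.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n_controls = 0L, n_trios = 0L, regions = NULL,
                       n_regions = 100L, spiked_events = list(),
                       mean_depth = 30, noise = c("negbin", "poisson", "none"),
                       dispersion = 400, read_length = 150L,
                       region_effect_sd = 0.3, sample_effect_sd = 0.1,
                       background_floor_frac = 0.01, de_novo_rate = 0,
                       force_parent_het = FALSE, seed) {
  noise <- match.arg(noise)
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (mean_depth <= 0) stop("mean_depth must be positive")
  if (is.null(regions)) regions <- sim_regions(n_regions)
  for (ev in spiked_events) {
    if (!all(ev$region_ids %in% regions$region_id))
      stop("spiked event references unknown region ids")
    if (ev$p < 0 || ev$p >= 1) stop("spiked allele frequency must be in [0, 1)")
  }
  structure(list(n_controls = as.integer(n_controls),
                 n_trios = as.integer(n_trios), regions = regions,
                 spiked_events = spiked_events, mean_depth = mean_depth,
                 noise = noise, dispersion = dispersion,
                 read_length = as.integer(read_length),
                 region_effect_sd = region_effect_sd,
                 sample_effect_sd = sample_effect_sd,
                 background_floor_frac = background_floor_frac,
                 de_novo_rate = de_novo_rate,
                 force_parent_het = isTRUE(force_parent_het),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Region effects are a property of the region (mappability, GC), not of a
# cohort: two cohorts simulated from the same config share them, so a
# control cohort can serve as normalization reference for a case cohort.
region_effects <- function(config) {
  set.seed(config$seed)
  stats::rlnorm(nrow(config$regions),
                meanlog = -config$region_effect_sd^2 / 2,
                sdlog = config$region_effect_sd)
}

# copies retained -> expected depth -> observed depth for all cells;
# e is the shared per-region effect vector, other draws use the current
# RNG stream
render_depth <- function(config, cn_true, sample_ids, e) {
  regions <- config$regions
  n <- length(sample_ids); m <- nrow(regions)
  g <- stats::rlnorm(n, meanlog = -config$sample_effect_sd^2 / 2,
                     sdlog = config$sample_effect_sd)
  diploid <- config$mean_depth * outer(g, e)
  mu <- diploid * cn_true / 2
  floor_d <- config$background_floor_frac * diploid
  mu[cn_true == 0L] <- floor_d[cn_true == 0L]
  if (config$noise == "none") {
    depth <- mu
  } else {
    len <- matrix(regions$end - regions$start, n, m, byrow = TRUE)
    reads_mu <- mu * len / config$read_length
    counts <- switch(config$noise,
      poisson = stats::rpois(n * m, reads_mu),
      negbin = stats::rnbinom(n * m, mu = reads_mu, size = config$dispersion))
    depth <- matrix(counts, n, m) * config$read_length / len
  }
  dimnames(depth) <- list(sample_ids, regions$region_id)
  depth
}

spiked_event_table <- function(config) {
  regions <- config$regions
  evs <- config$spiked_events
  if (!length(evs))
    return(data.frame(event_id = character(), chrom = character(),
                      start = integer(), end = integer(), p = numeric(),
                      stringsAsFactors = FALSE))
  idx <- lapply(evs, function(ev) match(ev$region_ids, regions$region_id))
  data.frame(event_id = sprintf("E%02d", seq_along(evs)),
             chrom = vapply(idx, function(i) regions$chrom[i[1]], ""),
             start = vapply(idx, function(i) min(regions$start[i]), integer(1)),
             end = vapply(idx, function(i) max(regions$end[i]), integer(1)),
             p = vapply(evs, function(ev) ev$p, numeric(1)),
             stringsAsFactors = FALSE)
}

#' Simulate a control cohort depth matrix with known deletion genotypes
#'
#' @param config a [sim_config] with \code{n_controls >= 1}.
#' @return List with \code{depth} (samples-by-regions matrix) and
#'   \code{truth}: \code{genotypes} (samples-by-events matrix of copies
#'   retained), \code{cn_true} (samples-by-regions), \code{events} (spiked
#'   event table with realized \code{fdel} = heterozygous-carrier fraction),
#'   and \code{regions}.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"), config$n_controls >= 1)
  e <- region_effects(config)
  set.seed(config$seed + 1L)
  ids <- sprintf("C%05d", seq_len(config$n_controls))
  geno <- founder_genotypes(config, length(ids))
  rownames(geno) <- ids
  cn_true <- genotype_to_cn(config, geno, ids)
  depth <- render_depth(config, cn_true, ids, e)
  evt <- spiked_event_table(config)
  evt$fdel <- if (nrow(evt)) colMeans(geno == 1L) else numeric()
  evt$region_ids <- lapply(config$spiked_events, `[[`, "region_ids")
  list(depth = depth,
       truth = list(genotypes = geno, cn_true = cn_true, events = evt,
                    regions = config$regions))
}

#' Simulate a trio cohort with Mendelian transmission
#'
#' Parent genotypes are Hardy-Weinberg draws at each spiked event's allele
#' frequency (or forced heterozygous); each child inherits one allele from
#' each parent uniformly at random, then optionally loses one copy de novo
#' at rate \code{de_novo_rate}. Sample ids are \code{T0001P/F/M} for
#' proband, father, mother.
#'
#' @param config a [sim_config] with \code{n_trios >= 1}.
#' @return List with \code{depth}, \code{trios} (a [trio_set]) and
#'   \code{truth} as in [simulate_cohort()], plus \code{trio_status}: per
#'   trio and event, the copies retained of proband/father/mother, whether
#'   the trio is a true inherited-biallelic (0,1,1) at that event, and
#'   whether a de novo loss was injected.
#' @export
simulate_trios <- function(config) {
  stopifnot(inherits(config, "sim_config"), config$n_trios >= 1)
  e <- region_effects(config)
  set.seed(config$seed + 2L)
  nt <- config$n_trios
  pid <- sprintf("T%04dP", seq_len(nt))
  fid <- sprintf("T%04dF", seq_len(nt))
  mid <- sprintf("T%04dM", seq_len(nt))
  evs <- config$spiked_events
  ne <- length(evs)
  gf <- founder_genotypes(config, nt)  # copies retained, trios x events
  gm <- founder_genotypes(config, nt)
  gp <- matrix(2L, nt, ne)
  dn <- matrix(FALSE, nt, ne)
  for (j in seq_len(max(ne, 0))) {
    del_f <- (2L - gf[, j]) / 2  # P(transmit deleted allele)
    del_m <- (2L - gm[, j]) / 2
    inherited_del <- stats::rbinom(nt, 1, del_f) + stats::rbinom(nt, 1, del_m)
    gp[, j] <- 2L - inherited_del
    if (config$de_novo_rate > 0) {
      hit <- stats::runif(nt) < config$de_novo_rate & gp[, j] > 0L
      gp[hit, j] <- gp[hit, j] - 1L
      dn[, j] <- hit
    }
  }
  ids <- c(pid, fid, mid)
  geno <- rbind(gp, gf, gm)
  rownames(geno) <- ids
  if (ne) colnames(geno) <- sprintf("E%02d", seq_len(ne))
  cn_true <- genotype_to_cn(config, geno, ids)
  depth <- render_depth(config, cn_true, ids, e)
  evt <- spiked_event_table(config)
  evt$region_ids <- lapply(evs, `[[`, "region_ids")
  status <- if (ne) data.frame(
    proband_id = rep(pid, ne), father_id = rep(fid, ne),
    mother_id = rep(mid, ne),
    event_id = rep(sprintf("E%02d", seq_len(ne)), each = nt),
    proband_copies = as.vector(gp), father_copies = as.vector(gf),
    mother_copies = as.vector(gm),
    is_011 = as.vector(gp == 0L & gf == 1L & gm == 1L),
    de_novo = as.vector(dn), stringsAsFactors = FALSE)
  else data.frame(proband_id = character(), father_id = character(),
                  mother_id = character(), event_id = character(),
                  proband_copies = integer(), father_copies = integer(),
                  mother_copies = integer(), is_011 = logical(),
                  de_novo = logical(), stringsAsFactors = FALSE)
  trios <- trio_set(data.frame(family_id = sprintf("FAM%04d", seq_len(nt)),
                               proband_id = pid, father_id = fid,
                               mother_id = mid, stringsAsFactors = FALSE))
  list(depth = depth, trios = trios,
       truth = list(genotypes = geno, cn_true = cn_true, events = evt,
                    trio_status = status, regions = config$regions))
}

# Hardy-Weinberg founder draws: copies retained (2 - deleted alleles),
# n samples x n events; forced het gives exactly one deleted allele
founder_genotypes <- function(config, n) {
  evs <- config$spiked_events
  geno <- matrix(2L, n, length(evs))
  for (j in seq_along(evs)) {
    geno[, j] <- if (config$force_parent_het) 1L
                 else 2L - stats::rbinom(n, 2, evs[[j]]$p)
  }
  if (length(evs)) colnames(geno) <- sprintf("E%02d", seq_along(evs))
  geno
}

# expand per-event copies to a per-region true CN matrix
genotype_to_cn <- function(config, geno, sample_ids) {
  regions <- config$regions
  cn <- matrix(2L, length(sample_ids), nrow(regions),
               dimnames = list(sample_ids, regions$region_id))
  for (j in seq_along(config$spiked_events))
    cn[, config$spiked_events[[j]]$region_ids] <- geno[, j]
  cn
}
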