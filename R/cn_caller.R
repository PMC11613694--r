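#' Normalize a depth matrix to diploid-scaled dosage
#'
#' Two-stage median normalization. Stage 1 removes library-size differences:
#' each sample's depths are divided by that sample's median depth across
#' regions. Stage 2 removes region-specific effects (length-free mappability,
#' GC, capture bias): each region's stage-1 ratios are divided by the median
#' ratio across a reference cohort (all samples by default), then scaled by 2
#' so that a two-copy region sits at dosage d = 2. Medians are robust to the
#' rare deletion carriers the pipeline targets. Regions whose reference
#' baseline falls below \code{min_region_median} carry no usable signal
#' (unmappable / uncovered everywhere) and are masked.
#'
#' @param depths samples-by-regions non-negative matrix (see
#'   [build_depth_matrix()]).
#' @param reference_samples optional character vector of sample ids defining
#'   the region baseline cohort; defaults to all samples.
#' @param min_region_median baseline threshold below which a region is
#'   masked (default 0.1, i.e. a region with under 10% of a typical region's
#'   normalized depth).
#' @return A \code{ratio_matrix}: list with \code{ratio} (samples-by-regions
#'   dosage matrix, d = 2 means diploid), \code{mask} (named logical per
#'   region, TRUE = uninformative), \code{sample_median} and
#'   \code{region_baseline} diagnostics.
#' @export
normalize_depth_matrix <- function(depths, reference_samples = NULL,
                                   min_region_median = 0.1) {
  stopifnot(is.matrix(depths), nrow(depths) >= 2, ncol(depths) >= 2)
  if (any(!is.finite(depths)) || any(depths < 0))
    stop("depth matrix must be finite and non-negative")
  m_s <- apply(depths, 1, stats::median)
  zero <- m_s == 0
  if (any(zero))
    stop("sample(s) with zero median depth (no usable coverage): ",
         paste(rownames(depths)[zero], collapse = ", "))
  r1 <- depths / m_s
  if (is.null(reference_samples)) reference_samples <- rownames(depths)
  missing_ref <- setdiff(reference_samples, rownames(depths))
  if (length(missing_ref))
    stop("reference sample(s) not in matrix: ",
         paste(missing_ref, collapse = ", "))
  c_r <- apply(r1[reference_samples, , drop = FALSE], 2, stats::median)
  mask <- c_r < min_region_median
  d <- sweep(r1, 2, c_r, "/") * 2
  d[, mask] <- NA_real_
  names(mask) <- colnames(depths)
  structure(list(ratio = d, mask = mask, sample_median = m_s,
                 region_baseline = c_r),
            class = "ratio_matrix")
}

#' @export
print.ratio_matrix <- function(x, ...) {
  cat(sprintf("ratio_matrix: %d samples x %d regions (%d masked)\n",
              nrow(x$ratio), ncol(x$ratio), sum(x$mask)))
  invisible(x)
}

#' Call integer copy numbers from diploid-scaled dosage
#'
#' Nearest-integer binning with half-integer edges: dosage d < 0.5 is copy
#' number 0 (homozygous deletion), and k - 0.5 <= d < k + 0.5 is copy number
#' k, capped at \code{cn_max}. A dosage sitting exactly on an edge is
#' assigned upward (d = 0.5 calls CN 1). Masked regions propagate as NA.
#'
#' @param ratios a \code{ratio_matrix} from [normalize_depth_matrix()], or a
#'   plain dosage matrix (then nothing is masked).
#' @param bins strictly increasing numeric vector of bin edges; edge
#'   \code{bins[k]} separates CN k-1 from CN k. Default
#'   \code{c(0.5, 1.5, ..., cn_max - 0.5)}.
#' @param cn_max cap on reported copy number (default 4; amplification
#'   detail is not the pipeline's subject).
#' @return A \code{cn_matrix}: integer samples-by-regions matrix (NA at
#'   masked regions) with attributes \code{mask} (per-region logical) and
#'   \code{distance} (|d - CN| per unmasked cell, for triage).
#' @export
call_copy_numbers <- function(ratios, bins = NULL, cn_max = 4L) {
  if (inherits(ratios, "ratio_matrix")) {
    d <- ratios$ratio
    mask <- ratios$mask
  } else {
    d <- ratios
    mask <- stats::setNames(rep(FALSE, ncol(d)), colnames(d))
  }
  if (is.null(bins)) bins <- seq(0.5, cn_max - 0.5, by = 1)
  if (is.unsorted(bins, strictly = TRUE))
    stop("bin edges must be strictly increasing")
  unmasked <- d[, !mask, drop = FALSE]
  if (any(!is.finite(unmasked)))
    stop("non-finite dosage at unmasked region(s)")
  cn <- matrix(findInterval(d, bins), nrow = nrow(d), dimnames = dimnames(d))
  cn <- pmin(cn, as.integer(cn_max))
  cn[, mask] <- NA_integer_
  storage.mode(cn) <- "integer"
  dist <- abs(d - cn)
  structure(cn, mask = mask, distance = dist, class = c("cn_matrix", "matrix"))
}

#' @export
print.cn_matrix <- function(x, ...) {
  mask <- attr(x, "mask")
  cat(sprintf("cn_matrix: %d samples x %d regions (%d masked)\n",
              nrow(x), ncol(x), sum(mask)))
  tab <- table(factor(x[, !mask, drop = FALSE], levels = 0:max(4, x, na.rm = TRUE)))
  cat("CN counts:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

# region mask vector of a cn_matrix (all-FALSE for a plain matrix)
cn_mask <- function(cn) {
  mask <- attr(cn, "mask")
  if (is.null(mask)) mask <- stats::setNames(rep(FALSE, ncol(cn)), colnames(cn))
  mask
}
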