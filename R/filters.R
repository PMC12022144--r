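#' Select test SNPs for the selection scans
#'
#' Applies the standard scan filters: minor allele frequency between
#' `maf_min` and `maf_max` (MAF taken as `min(f, 1 - f)` of the polarized
#' derived frequency), all three diploid genotype classes present in the
#' sample, and position outside excluded intervals (e.g. centromeres).
#' Singletons can never be test SNPs, but they remain available to the
#' singleton-density scorer. The selection is idempotent and independent
#' of site order.
#'
#' @param sites a [site_table()].
#' @param panel the matching [phased_panel()] (for genotype classes).
#' @param maf_min,maf_max MAF bounds (defaults 0.05 and 0.95).
#' @param excluded optional `data.frame(chrom, start, end)` of 0-based
#'   half-open intervals to exclude.
#' @return integer vector of selected site indices (possibly empty, with
#'   a warning so downstream scans can skip).
#' @export
select_test_snps <- function(sites, panel, maf_min = 0.05, maf_max = 0.95,
                             excluded = NULL) {
  stopifnot(inherits(sites, "SiteTable"), inherits(panel, "PhasedPanel"))
  f <- sites$derived_freq
  maf <- pmin(f, 1 - f)
  ok <- maf >= maf_min & maf <= maf_max & f < 1 & f > 0 &
    !sites$is_singleton
  if (any(ok)) {
    G <- genotype_dosage(panel, sites$site[ok])
    three <- vapply(seq_len(ncol(G)), function(j) {
      g <- G[, j]
      any(g == 0L) && any(g == 1L) && any(g == 2L)
    }, logical(1))
    ok[which(ok)[!three]] <- FALSE
  }
  if (!is.null(excluded) && nrow(excluded) > 0) {
    excl <- if ("chrom" %in% names(excluded))
      excluded[excluded$chrom == sites$chrom[1], , drop = FALSE]
    else excluded
    if (nrow(excl) > 0)
      ok <- ok & !in_intervals(sites$position_bp, excl)
  }
  ok <- ok & !sites$in_excluded_region
  idx <- sites$site[ok]
  if (length(idx) == 0L)
    warning("no sites pass the test-SNP filters; downstream scans will skip")
  idx
}
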