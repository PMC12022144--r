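#' Extended haplotype homozygosity decay from a core site
#'
#' EHH at extension distance x is the probability that two haplotypes
#' drawn at random without replacement are identical over all sites from
#' the core through x inclusive:
#' `EHH(x) = sum_h C(n_h, 2) / C(n, 2)` over the multiplicities `n_h` of
#' the distinct extended haplotype strings. It is computed over ALL
#' haplotypes of the panel (population-level EHH, the convention used for
#' cross-population comparison), evaluated at each successive site. The
#' curve starts at 1 at distance 0 and is non-increasing.
#'
#' @param panel a [phased_panel()] with at least 2 haplotypes.
#' @param core site index of the core SNP.
#' @param direction `"left"` or `"right"`.
#' @return An `EHHCurve`: `data.frame(distance_cM, ehh)` with attributes
#'   `core` and `direction`. A core at the chromosome edge yields a
#'   length-1 curve (EHH = 1 at distance 0).
#' @export
ehh <- function(panel, core, direction = c("right", "left")) {
  stopifnot(inherits(panel, "PhasedPanel"))
  direction <- match.arg(direction)
  m <- n_sites(panel)
  if (core < 1 || core > m) stop("core site index out of range")
  if (n_haplotypes(panel) < 2) stop("need at least 2 haplotypes")
  dir <- if (direction == "right") 1L else -1L
  vals <- ehh_curve_cpp(panel$haplotypes, core - 1L, dir)
  idx <- core + dir * (seq_along(vals) - 1L)
  out <- data.frame(distance_cM = abs(panel$positions_cM[idx] -
                                        panel$positions_cM[core]),
                    ehh = as.numeric(vals))
  attr(out, "core") <- core
  attr(out, "direction") <- direction
  class(out) <- c("EHHCurve", "data.frame")
  out
}

#' Integrated haplotype homozygosity at a core site
#'
#' Trapezoidal integral of the EHH curve over genetic distance, left plus
#' right, each side truncated at the first site where EHH drops below
#' `truncation` (with a partial trapezoid to the linearly interpolated
#' crossing point). `truncation = 0` integrates the full curve. An iHH of
#' 0 (immediate decay on both sides) is a valid value.
#'
#' @param panel a [phased_panel()].
#' @param core core site index (may be a vector).
#' @param truncation EHH truncation threshold (default 0.05).
#' @return numeric vector of iHH values in cM units.
#' @export
ihh <- function(panel, core, truncation = 0.05) {
  stopifnot(inherits(panel, "PhasedPanel"))
  if (any(core < 1 | core > n_sites(panel)))
    stop("core site index out of range")
  as.numeric(ihh_sites_cpp(panel$haplotypes, panel$positions_cM,
                           as.integer(core) - 1L, truncation))
}

#' Cross-population extended haplotype homozygosity (XP-EHH)
#'
#' Raw score `ln(iHH_A / iHH_B)` at each test site, standardized to mean
#' 0 and SD 1 over all defined test sites genome-wide (single bin), with
#' two-sided normal p-values. Sites where either population's iHH is 0
#' are undefined (NA) and counted in the attached log. Positive scores
#' indicate longer haplotypes -- a recent sweep -- in population A
#' relative to B.
#'
#' @param panel_a,panel_b two [phased_panel()]s on the same site
#'   coordinates (intersect beforehand).
#' @param test_sites site indices to score (default: all sites).
#' @param truncation EHH truncation for [ihh()].
#' @param standardize set `FALSE` to return raw scores only (used when
#'   tracks from several chromosomes are standardized jointly).
#' @return A `ScoreTrack` data frame: `chrom`, `position_bp`, `site`,
#'   `raw`, `standardized`, `pvalue`; attribute `method = "XPEHH"`.
#' @export
xpehh <- function(panel_a, panel_b, test_sites = NULL, truncation = 0.05,
                  standardize = TRUE) {
  stopifnot(inherits(panel_a, "PhasedPanel"),
            inherits(panel_b, "PhasedPanel"))
  if (n_sites(panel_a) != n_sites(panel_b) ||
      any(panel_a$positions_bp != panel_b$positions_bp))
    stop("panels must share site coordinates; intersect them first")
  if (is.null(test_sites)) test_sites <- seq_len(n_sites(panel_a))
  ihh_a <- ihh(panel_a, test_sites, truncation)
  ihh_b <- ihh(panel_b, test_sites, truncation)
  raw <- rep(NA_real_, length(test_sites))
  defined <- ihh_a > 0 & ihh_b > 0
  raw[defined] <- log(ihh_a[defined] / ihh_b[defined])
  out <- data.frame(chrom = panel_a$chrom,
                    position_bp = panel_a$positions_bp[test_sites],
                    site = test_sites,
                    raw = raw,
                    standardized = NA_real_,
                    pvalue = NA_real_)
  attr(out, "method") <- "XPEHH"
  attr(out, "log") <- list(n_undefined = sum(!defined),
                           n_defined = sum(defined))
  class(out) <- c("ScoreTrack", "data.frame")
  if (standardize) out <- standardize_track(out)
  out
}

#' Sites passing a pooled MAF filter across two panels
#'
#' For cross-population haplotype scoring the two panels should carry
#' the variants that are common in the POOLED sample (as when two
#' cohorts are merged and then MAF-filtered together): scoring a panel
#' only on the other population's variants makes it spuriously
#' homozygous. Returns the site indices whose pooled minor allele
#' frequency is at least `maf_min`.
#'
#' @param panel_a,panel_b panels on shared site coordinates.
#' @param maf_min pooled MAF threshold (default 0.05).
#' @return integer vector of site indices.
#' @export
pooled_maf_sites <- function(panel_a, panel_b, maf_min = 0.05) {
  if (n_sites(panel_a) != n_sites(panel_b))
    stop("panels must share site coordinates")
  dc <- colSums(panel_a$haplotypes) + colSums(panel_b$haplotypes)
  f <- dc / (n_haplotypes(panel_a) + n_haplotypes(panel_b))
  which(pmin(f, 1 - f) >= maf_min)
}

#' XP-EHH scan of a simulated target/outgroup pair
#'
#' Convenience wrapper applying the standard cross-population scoring
#' protocol to a [simulate_panel_pair()] result: test SNPs are the
#' target population's filtered sites that are also common (MAF >=
#' `maf_min`) in the outgroup; haplotype homozygosity is computed on the
#' pooled-MAF panel (see [pooled_maf_sites()]).
#'
#' @param pair a [simulate_panel_pair()] result.
#' @param maf_min MAF threshold for test SNPs and the pooled panel.
#' @param truncation EHH truncation (see [ihh()]).
#' @param standardize standardize the returned track (set `FALSE` when
#'   tracks from several pairs are standardized jointly).
#' @return a `ScoreTrack`; `site` indexes the pair's shared coordinates.
#' @export
xpehh_pair_scan <- function(pair, maf_min = 0.05, truncation = 0.05,
                            standardize = TRUE) {
  ts <- select_test_snps(pair$sites_a, pair$panel_a, maf_min = maf_min)
  fb <- pair$sites_b$derived_freq[ts]
  ts <- ts[pmin(fb, 1 - fb) >= maf_min]
  keep <- sort(union(pooled_maf_sites(pair$panel_a, pair$panel_b, maf_min),
                     ts))
  pa <- subset_panel(pair$panel_a, pair$panel_a$positions_bp[keep])
  pb <- subset_panel(pair$panel_b, pair$panel_b$positions_bp[keep])
  tr <- xpehh(pa, pb, match(ts, keep), truncation = truncation,
              standardize = standardize)
  tr$site <- ts
  tr
}

#' Thin test SNPs to a minimum spacing
#'
#' Greedy left-to-right thinning: keeps each site only if it lies at
#' least `min_gap_bp` beyond the last kept site. Used to obtain
#' quasi-independent test SNPs for calibration checks on linked data.
#'
#' @param positions_bp site positions of the panel.
#' @param sites candidate site indices (ordered by position).
#' @param min_gap_bp minimum spacing in bp.
#' @return thinned integer vector of site indices.
#' @export
thin_test_snps <- function(positions_bp, sites, min_gap_bp) {
  keep <- integer(0)
  last <- -Inf
  for (i in sites) {
    if (positions_bp[i] - last >= min_gap_bp) {
      keep <- c(keep, i)
      last <- positions_bp[i]
    }
  }
  keep
}

#' Standardize a raw score track genome-wide
#'
#' Single-bin standardization: `(raw - mean) / SD` over all defined
#' sites, with two-sided normal p-values. Used for XP-EHH; the singleton
#' density score uses frequency-binned standardization instead
#' (see [normalize_sds()]).
#'
#' @param track a `ScoreTrack` (possibly row-bound across chromosomes).
#' @return the track with `standardized` and `pvalue` filled in.
#' @export
standardize_track <- function(track) {
  ok <- !is.na(track$raw)
  if (sum(ok) < 2) stop("fewer than 2 defined sites; cannot standardize")
  mu <- mean(track$raw[ok])
  sigma <- sd(track$raw[ok])
  if (sigma == 0) stop("degenerate score track: zero variance")
  track$standardized <- (track$raw - mu) / sigma
  track$pvalue <- 2 * pnorm(-abs(track$standardized))
  track
}

#' @export
print.ScoreTrack <- function(x, ...) {
  cat(sprintf("ScoreTrack (%s): %d sites, %d defined\n",
              attr(x, "method") %||% "?", nrow(x), sum(!is.na(x$raw))))
  print.data.frame(utils::head(x, 6L))
  if (nrow(x) > 6L) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
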