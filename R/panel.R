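#' Phased haplotype panel
#'
#' A panel of `n_hap` phased haplotypes at `m` polarized biallelic sites.
#' Allele codes are 0 = ancestral, 1 = derived. Haplotypes `2i - 1` and
#' `2i` belong to diploid individual `i`; the haplotype count must be even
#' so this pairing is preserved. Physical positions are strictly
#' increasing; genetic positions are non-decreasing and aligned 1:1 with
#' the physical ones.
#'
#' @param haplotypes integer matrix (`n_hap` x `m`) of 0/1 allele codes.
#' @param positions_bp numeric vector of physical positions (bp), strictly
#'   increasing. Positions from the continuous-sequence simulator may be
#'   fractional; file writers round at the boundary.
#' @param positions_cM numeric vector of genetic positions, non-decreasing.
#'   Defaults to a uniform 1 cM/Mb map (with a warning) when omitted.
#' @param chrom chromosome label.
#' @param sample_ids diploid sample identifiers (`n_hap / 2` of them).
#' @return An object of class `PhasedPanel`: a list with elements
#'   `haplotypes`, `positions_bp`, `positions_cM`, `chrom`, `sample_ids`.
#' @export
phased_panel <- function(haplotypes, positions_bp, positions_cM = NULL,
                         chrom = "1", sample_ids = NULL) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  n_hap <- nrow(haplotypes)
  m <- ncol(haplotypes)
  if (n_hap %% 2L != 0L)
    stop("haplotype count must be even (diploid pairing)")
  if (length(positions_bp) != m)
    stop("positions_bp length does not match site count")
  if (m > 1L && any(diff(positions_bp) <= 0))
    stop("positions_bp must be strictly increasing")
  if (m > 0L && !all(haplotypes %in% c(0L, 1L)))
    stop("alleles must be 0 (ancestral) or 1 (derived)")
  if (is.null(positions_cM)) {
    if (m > 0L)
      warning("no genetic map supplied; assuming uniform 1 cM/Mb")
    positions_cM <- positions_bp * 1e-6
  }
  if (length(positions_cM) != m)
    stop("positions_cM length does not match site count")
  if (m > 1L && any(diff(positions_cM) < 0))
    stop("positions_cM must be non-decreasing")
  if (is.null(sample_ids))
    sample_ids <- sprintf("ind%03d", seq_len(n_hap %/% 2L))
  if (length(sample_ids) != n_hap %/% 2L)
    stop("need one sample id per diploid")
  structure(list(haplotypes = haplotypes,
                 positions_bp = as.numeric(positions_bp),
                 positions_cM = as.numeric(positions_cM),
                 chrom = as.character(chrom),
                 sample_ids = as.character(sample_ids)),
            class = "PhasedPanel")
}

#' @export
print.PhasedPanel <- function(x, ...) {
  cat(sprintf("PhasedPanel: %d haplotypes (%d diploids), %d sites, chrom %s\n",
              nrow(x$haplotypes), nrow(x$haplotypes) %/% 2L,
              ncol(x$haplotypes), x$chrom))
  if (ncol(x$haplotypes) > 0)
    cat(sprintf("  span: %.0f-%.0f bp (%.3f-%.3f cM)\n",
                min(x$positions_bp), max(x$positions_bp),
                min(x$positions_cM), max(x$positions_cM)))
  invisible(x)
}

n_haplotypes <- function(panel) nrow(panel$haplotypes)
n_diploids <- function(panel) nrow(panel$haplotypes) %/% 2L
n_sites <- function(panel) ncol(panel$haplotypes)

#' Per-site metadata table for a phased panel
#'
#' Derived-allele counts and frequencies, singleton flags and owners.
#' A singleton is a site whose derived allele occurs on exactly one
#' haplotype; the diploid carrying that haplotype "owns" it. Sites
#' falling inside excluded intervals (e.g. centromeres) are flagged.
#'
#' @param panel a [phased_panel()].
#' @param excluded optional `data.frame(start, end)` of 0-based half-open
#'   excluded intervals on the panel's chromosome (see [read_bed()]).
#' @return A `data.frame` of class `SiteTable` with columns
#'   `site`, `chrom`, `position_bp`, `ancestral_allele`, `derived_allele`,
#'   `derived_count`, `derived_freq`, `is_singleton`, `singleton_owner`,
#'   `in_excluded_region`.
#' @export
site_table <- function(panel, excluded = NULL) {
  stopifnot(inherits(panel, "PhasedPanel"))
  H <- panel$haplotypes
  n_hap <- nrow(H)
  dc <- as.integer(colSums(H))
  f <- dc / n_hap
  is_singleton <- dc == 1L
  owner <- rep(NA_integer_, ncol(H))
  if (any(is_singleton)) {
    hap_idx <- apply(H[, is_singleton, drop = FALSE], 2L, which.max)
    owner[is_singleton] <- as.integer((hap_idx + 1L) %/% 2L)
  }
  anc <- attr(panel, "ancestral_allele")
  der <- attr(panel, "derived_allele")
  if (is.null(anc)) anc <- rep("A", ncol(H))
  if (is.null(der)) der <- rep("G", ncol(H))
  excl <- rep(FALSE, ncol(H))
  if (!is.null(excluded) && nrow(excluded) > 0)
    excl <- in_intervals(panel$positions_bp, excluded)
  out <- data.frame(site = seq_len(ncol(H)),
                    chrom = rep(panel$chrom, ncol(H)),
                    position_bp = panel$positions_bp,
                    ancestral_allele = anc,
                    derived_allele = der,
                    derived_count = dc,
                    derived_freq = f,
                    is_singleton = is_singleton,
                    singleton_owner = owner,
                    in_excluded_region = excl,
                    stringsAsFactors = FALSE)
  class(out) <- c("SiteTable", "data.frame")
  out
}

# positions (1-based bp) falling in any 0-based half-open interval
in_intervals <- function(pos, intervals) {
  hit <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(intervals)))
    hit <- hit | (pos > intervals$start[i] & pos <= intervals$end[i])
  hit
}

#' Diploid genotype dosages at given sites
#'
#' Derived-allele dosage (0, 1 or 2) of each diploid at each requested
#' site, computed by summing the two phased haplotypes of each individual.
#'
#' @param panel a [phased_panel()].
#' @param sites site indices (default all).
#' @return integer matrix, diploids x sites.
#' @export
genotype_dosage <- function(panel, sites = seq_len(n_sites(panel))) {
  H <- panel$haplotypes[, sites, drop = FALSE]
  odd <- seq(1L, nrow(H), by = 2L)
  G <- H[odd, , drop = FALSE] + H[odd + 1L, , drop = FALSE]
  rownames(G) <- panel$sample_ids
  G
}
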