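#' Tip model for the singleton density score
#'
#' The scorer models singletons as Poisson processes along each
#' haplotype's terminal ("tip") branch: an individual whose two
#' haplotypes carry alleles `a1, a2` at the test SNP sees a
#' nearest-own-singleton distance on each side that is exponential with
#' rate `1/m_a1 + 1/m_a2`, where `m_A` and `m_D` are the mean
#' nearest-singleton distance scales of ancestral- and derived-allele
#' haplotypes (inversely proportional to the mean tip lengths `mu_A`,
#' `mu_D`). The two sides sum to a Gamma(2, rate) total; the shape 2 may
#' be replaced per DAF bin and genotype by a gamma-shapes table inferred
#' from a demographic model (supplied as a config artifact, see
#' [read_gamma_shapes()]). Censored sides contribute survival terms.
#'
#' @param shapes optional gamma-shapes `data.frame(f_bin, genotype,
#'   shape)`; when absent, shape 2 (the exponential-tip model) is used
#'   everywhere.
#' @param observability placeholder hook for per-variant observability
#'   weights; the default treats the observability of each variant as
#'   equal (a no-op, the convention used for the cohort scan).
#' @return a `TipModel` list.
#' @export
tip_model <- function(shapes = NULL, observability = NULL) {
  if (!is.null(shapes))
    stopifnot(all(c("f_bin", "genotype", "shape") %in% names(shapes)),
              all(shapes$shape > 0))
  structure(list(shapes = shapes, observability = observability),
            class = "TipModel")
}

#' Read a gamma-shapes table
#'
#' TSV with columns `f_bin` (lower edge of the 0.01-wide DAF bin),
#' `genotype` (0/1/2) and `shape`.
#'
#' @param path file path.
#' @return a [tip_model()] carrying the table.
#' @export
read_gamma_shapes <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  tip_model(shapes = tab)
}

# per-individual total-distance gamma shape kappa(f, g); default 2
kappa_lookup <- function(model, f, genotypes) {
  if (is.null(model) || is.null(model$shapes))
    return(rep(2, length(genotypes)))
  tab <- model$shapes
  fb <- floor(f * 100) / 100
  k <- rep(2, length(genotypes))
  for (g in 0:2) {
    row <- which(abs(tab$f_bin - fb) < 1e-9 & tab$genotype == g)
    if (length(row) == 1L) k[genotypes == g] <- tab$shape[row]
  }
  k
}

#' Collect per-individual nearest-singleton distances at a test SNP
#'
#' For each diploid individual, the distance from the test SNP to the
#' nearest singleton OWNED BY THAT INDIVIDUAL strictly to the left and
#' strictly to the right. When no owned singleton exists on a side, the
#' distance to the analysis boundary is recorded and the side is flagged
#' censored. Distances are in bp and strictly positive.
#'
#' @param panel a [phased_panel()].
#' @param sites the matching [site_table()] (provides singleton owners).
#' @param test_snp site index of the test SNP (must not be a singleton).
#' @param boundaries analysis-window limits `c(left, right)` in bp;
#'   defaults to the panel's first and last site positions.
#' @return A `SingletonDistances` data frame: `individual`, `genotype`,
#'   `left_distance`, `right_distance`, `left_censored`, `right_censored`.
#' @export
collect_singleton_distances <- function(panel, sites, test_snp,
                                        boundaries = NULL) {
  stopifnot(inherits(panel, "PhasedPanel"), inherits(sites, "SiteTable"))
  if (sites$is_singleton[test_snp])
    stop("test SNP is itself a singleton and cannot be scored")
  if (is.null(boundaries))
    boundaries <- range(panel$positions_bp)
  pos0 <- sites$position_bp[test_snp]
  nd <- n_diploids(panel)
  sing <- sites[sites$is_singleton, c("position_bp", "singleton_owner")]
  g <- as.integer(genotype_dosage(panel, test_snp))
  left <- rep(pmax(pos0 - boundaries[1], 1), nd)
  right <- rep(pmax(boundaries[2] - pos0, 1), nd)
  lcen <- rep(TRUE, nd)
  rcen <- rep(TRUE, nd)
  if (nrow(sing) > 0) {
    by_owner <- split(sing$position_bp, sing$singleton_owner)
    for (ow in names(by_owner)) {
      i <- as.integer(ow)
      p <- by_owner[[ow]]
      lo <- p[p < pos0]
      hi <- p[p > pos0]
      if (length(lo)) { left[i] <- pos0 - max(lo); lcen[i] <- FALSE }
      if (length(hi)) { right[i] <- min(hi) - pos0; rcen[i] <- FALSE }
    }
  }
  out <- data.frame(individual = seq_len(nd), genotype = g,
                    left_distance = left, right_distance = right,
                    left_censored = lcen, right_censored = rcen)
  class(out) <- c("SingletonDistances", "data.frame")
  out
}

#' Raw singleton density score at one test SNP
#'
#' Maximum-likelihood contrast of singleton-distance scales between
#' derived- and ancestral-allele haplotypes (see [tip_model()]). The
#' two-parameter likelihood is anchored by fixing the frequency-weighted
#' mean distance scale, `f * m_D + (1 - f) * m_A`, to its neutral
#' expectation estimated from the (genome-wide) mean total distance at
#' this DAF; a 1-D profile likelihood is then maximized over
#' `r = log(m_D / m_A) = log(mu_A / mu_D)`. Positive r means derived
#' tips are shorter, i.e. the derived allele has been rising.
#'
#' @param distances a [collect_singleton_distances()] table.
#' @param f derived allele frequency at the test SNP.
#' @param model a [tip_model()] (default: exponential tips, shape 2).
#' @param anchor_mean_distance genome-wide mean total (left + right)
#'   singleton distance for this DAF bin; when `NULL` it is estimated
#'   from `distances` itself.
#' @param r_bounds profile-likelihood search interval for r.
#' @return list with `r_hat`, `se` (curvature-based), `converged`,
#'   `loglik`. Non-convergence (boundary solutions or non-positive
#'   curvature) returns `converged = FALSE` with `r_hat = NA`.
#' @export
raw_sds <- function(distances, f, model = tip_model(),
                    anchor_mean_distance = NULL, r_bounds = c(-12, 12)) {
  g <- distances$genotype
  if (length(unique(g)) < 2)
    stop("need individuals in at least two genotype classes to identify r")
  kappa <- kappa_lookup(model, f, g)
  d_tot <- distances$left_distance + distances$right_distance
  if (is.null(anchor_mean_distance)) {
    ad <- sds_anchor_parts(distances, kappa)
    if (ad[2] == 0) stop("all singleton distances censored; no anchor")
    anchor_mean_distance <- ad[1] / ad[2]
  }
  m_hat <- anchor_mean_distance
  side_shape <- kappa / 2
  dl <- distances$left_distance
  dr <- distances$right_distance
  lc <- distances$left_censored
  rc <- distances$right_censored
  negll <- function(r) {
    denom <- (1 - f) + f * exp(r)
    m_a <- m_hat / denom
    m_d <- m_hat * exp(r) / denom
    rate <- (2 - g) / m_a + g / m_d
    ll <- ifelse(lc,
                 pgamma(dl, shape = side_shape, rate = rate,
                        lower.tail = FALSE, log.p = TRUE),
                 dgamma(dl, shape = side_shape, rate = rate, log = TRUE)) +
      ifelse(rc,
             pgamma(dr, shape = side_shape, rate = rate,
                    lower.tail = FALSE, log.p = TRUE),
             dgamma(dr, shape = side_shape, rate = rate, log = TRUE))
    -sum(ll)
  }
  opt <- optimize(negll, r_bounds)
  r_hat <- opt$minimum
  # curvature-based standard error from a central second difference
  h <- 1e-3
  d2 <- (negll(r_hat + h) - 2 * opt$objective + negll(r_hat - h)) / h^2
  at_boundary <- min(r_hat - r_bounds[1], r_bounds[2] - r_hat) < 0.05
  converged <- !at_boundary && is.finite(d2) && d2 > 0
  list(r_hat = if (converged) r_hat else NA_real_,
       se = if (converged) 1 / sqrt(d2) else NA_real_,
       converged = converged,
       loglik = -opt$objective)
}

#' @importFrom stats dgamma pgamma
NULL

# censoring-aware anchor ingredients: weighted total distance (exposure)
# and effective number of complete observations, so that the null mean
# total-distance scale is exposure/events (reduces to mean(2 d/kappa)
# without censoring)
sds_anchor_parts <- function(distances, kappa) {
  d_tot <- distances$left_distance + distances$right_distance
  u <- (!distances$left_censored) + (!distances$right_censored)
  c(exposure = sum(2 * d_tot / kappa), events = sum(u / 2))
}

#' Singleton density score scan over test SNPs
#'
#' Computes raw scores at every test SNP (anchoring each site's
#' likelihood with the genome-wide mean singleton distance of its DAF
#' bin) and standardizes them in derived-allele-frequency bins of width
#' 0.01 spanning 0.05-0.95 via [normalize_sds()].
#'
#' @param panel a [phased_panel()].
#' @param sites the matching [site_table()].
#' @param test_sites site indices from [select_test_snps()].
#' @param model a [tip_model()].
#' @param boundaries analysis-window limits in bp (see
#'   [collect_singleton_distances()]).
#' @param standardize set `FALSE` to return raw scores only (for joint
#'   multi-chromosome normalization; see [normalize_sds()]).
#' @return A `ScoreTrack` data frame with attribute `method = "SDS"` and
#'   a log listing undefined sites.
#' @export
sds_scan <- function(panel, sites, test_sites, model = tip_model(),
                     boundaries = NULL, standardize = TRUE) {
  out <- sds_scan_genome(list(list(panel = panel, sites = sites,
                                   test_sites = test_sites)),
                         model = model, boundaries = boundaries,
                         standardize = standardize)
  out
}

#' Genome-wide singleton density score scan
#'
#' Like [sds_scan()] but over several chromosomes at once: the per-bin
#' anchor (the neutral mean-distance scale) is pooled across ALL
#' chromosomes before any site is scored, and standardization bins span
#' the combined track, matching a genome-wide analysis.
#'
#' @param chroms list of `list(panel, sites, test_sites, boundaries)`
#'   entries, one per chromosome (`boundaries` optional per entry).
#' @param bin_anchor optional named vector of per-DAF-bin anchor scales
#'   (as attached to a previous track via `attr(track, "bin_anchor")`),
#'   e.g. to score additional chromosomes against an existing genome's
#'   anchors; bins absent from it fall back to this scan's own pooled
#'   anchors.
#' @inheritParams sds_scan
#' @return a combined `ScoreTrack` (one row per test SNP of every
#'   chromosome), with the per-bin anchors in `attr(, "bin_anchor")`.
#' @export
sds_scan_genome <- function(chroms, model = tip_model(), boundaries = NULL,
                            standardize = TRUE, bin_anchor = NULL) {
  collected <- lapply(chroms, function(ch) {
    ts <- ch$test_sites
    bnd <- ch$boundaries %||% boundaries
    dist_list <- lapply(ts, function(t)
      collect_singleton_distances(ch$panel, ch$sites, t, bnd))
    list(dist_list = dist_list, f = ch$sites$derived_freq[ts],
         pos = ch$sites$position_bp[ts], chrom = ch$panel$chrom, ts = ts)
  })
  f_all <- unlist(lapply(collected, `[[`, "f"))
  bin_all <- sds_bin_index(f_all)
  parts <- matrix(unlist(lapply(collected, function(co)
    vapply(seq_along(co$dist_list), function(i)
      sds_anchor_parts(co$dist_list[[i]],
                       kappa_lookup(model, co$f[i],
                                    co$dist_list[[i]]$genotype)),
      numeric(2)))), nrow = 2)
  own_anchor <- tapply(parts[1, ], bin_all, sum) /
    tapply(parts[2, ], bin_all, sum)
  if (!is.null(bin_anchor)) {
    missing_bins <- setdiff(names(own_anchor), names(bin_anchor))
    bin_anchor <- c(bin_anchor, own_anchor[missing_bins])
  } else {
    bin_anchor <- own_anchor
  }
  idx0 <- 0L
  tracks <- lapply(collected, function(co) {
    n <- length(co$ts)
    raw <- se <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      d <- co$dist_list[[i]]
      if (length(unique(d$genotype)) < 2) next
      b <- bin_all[idx0 + i]
      anc <- if (is.na(b)) NULL else unname(bin_anchor[as.character(b)])
      fit <- raw_sds(d, co$f[i], model, anchor_mean_distance = anc)
      if (fit$converged) { raw[i] <- fit$r_hat; se[i] <- fit$se }
    }
    idx0 <<- idx0 + n
    data.frame(chrom = co$chrom, position_bp = co$pos, site = co$ts,
               derived_freq = co$f, raw = raw, se = se,
               standardized = NA_real_, pvalue = NA_real_)
  })
  out <- do.call(rbind, tracks)
  attr(out, "method") <- "SDS"
  attr(out, "bin_anchor") <- bin_anchor
  attr(out, "log") <- list(n_undefined = sum(is.na(out$raw)),
                           n_defined = sum(!is.na(out$raw)))
  class(out) <- c("ScoreTrack", "data.frame")
  if (standardize) out <- normalize_sds(out)
  out
}

sds_bin_index <- function(f) {
  # bins [0.05, 0.06), ..., [0.94, 0.95]; sites outside get NA
  b <- floor(round(f, 10) * 100)
  b[b == 95 & f <= 0.95] <- 94
  b[f < 0.05 | f > 0.95] <- NA
  as.integer(b)
}

#' Standardize a raw SDS track in DAF bins
#'
#' Raw scores are standardized to mean 0 / SD 1 within derived-allele
#' frequency bins of width 0.01 spanning `[0.05, 0.95]`; bins holding
#' fewer than `min_bin_n` defined sites are merged with their right
#' neighbour (left at the end) before standardization, and the merges
#' are recorded in the log. P-values are two-sided standard normal.
#'
#' @param track a raw `ScoreTrack` from [sds_scan()] (needs columns
#'   `raw` and `derived_freq`); tracks from several chromosomes may be
#'   row-bound first for genome-wide normalization.
#' @param min_bin_n minimum defined sites per bin (default 2).
#' @return the track with `standardized` and `pvalue` filled in.
#' @export
normalize_sds <- function(track, min_bin_n = 2) {
  f <- track$derived_freq
  if (is.null(f)) stop("track lacks derived_freq; cannot bin")
  bin <- sds_bin_index(f)
  defined <- !is.na(track$raw) & !is.na(bin)
  if (sum(defined) < 2) stop("fewer than 2 defined sites to normalize")
  # merge underfilled bins rightwards (greedy), tail merges left
  ubins <- sort(unique(bin[defined]))
  counts <- as.integer(table(factor(bin[defined], levels = ubins)))
  gid_of_bin <- integer(length(ubins))
  g <- 1L; acc <- 0L
  for (j in seq_along(ubins)) {
    gid_of_bin[j] <- g
    acc <- acc + counts[j]
    if (acc >= min_bin_n) { g <- g + 1L; acc <- 0L }
  }
  if (acc > 0L && g > 1L)
    gid_of_bin[gid_of_bin == g] <- g - 1L
  # a group may still be degenerate (tied scores from shared singleton
  # neighbourhoods); keep absorbing such groups into a neighbour
  repeat {
    gid <- gid_of_bin[match(bin, ubins)]
    groups <- sort(unique(gid_of_bin))
    sds_g <- vapply(groups, function(gg)
      sd(track$raw[defined & gid == gg]), numeric(1))
    bad <- which(is.na(sds_g) | sds_g == 0)
    if (length(bad) == 0) break
    if (length(groups) == 1L)
      stop("degenerate DAF bin with zero score variance")
    b <- bad[1]
    into <- if (b < length(groups)) groups[b + 1L] else groups[b - 1L]
    gid_of_bin[gid_of_bin == groups[b]] <- into
  }
  merged <- length(ubins) - length(unique(gid_of_bin))
  gid <- gid_of_bin[match(bin, ubins)]
  z <- rep(NA_real_, nrow(track))
  for (gg in unique(gid[defined])) {
    sel <- defined & gid == gg
    mu <- mean(track$raw[sel])
    sigma <- sd(track$raw[sel])
    z[sel] <- (track$raw[sel] - mu) / sigma
  }
  track$standardized <- z
  track$pvalue <- 2 * pnorm(-abs(z))
  lg <- attr(track, "log") %||% list()
  lg$n_merged_bins <- merged
  attr(track, "log") <- lg
  track
}
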