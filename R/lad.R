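#' Per-site ancestry proportion track
#'
#' Proportion of haplotypes assigned to ancestry `k` at each site.
#'
#' @param am an [ancestry_matrix()].
#' @param ancestry ancestry label (string) or 0-based integer code.
#' @return `data.frame(chrom, position_bp, proportion)`.
#' @export
ancestry_proportion <- function(am, ancestry) {
  stopifnot(inherits(am, "AncestryMatrix"))
  if (is.character(ancestry)) {
    code <- match(ancestry, am$labels) - 1L
    if (is.na(code)) stop("unknown ancestry label: ", ancestry)
  } else {
    code <- as.integer(ancestry)
    if (code < 0L || code >= length(am$labels))
      stop("unknown ancestry code: ", ancestry)
  }
  if (nrow(am$codes) < 1) stop("need at least one haplotype")
  data.frame(chrom = am$chrom,
             position_bp = am$positions_bp,
             proportion = colMeans(am$codes == code))
}

#' Named local-ancestry-deviation thresholds
#'
#' The two cut-offs used for flagging deviated regions: `"strict"`
#' (4.42 SD) and `"lenient"` (3 SD).
#'
#' @param preset `"strict"` or `"lenient"`.
#' @return the threshold in SD units.
#' @export
lad_threshold <- function(preset = c("strict", "lenient")) {
  c(strict = 4.42, lenient = 3)[[match.arg(preset)]]
}

#' Local ancestry deviation scan
#'
#' Flags maximal contiguous runs of sites whose ancestry proportion
#' departs from the genome-wide mean by more than `threshold_sd`
#' standard deviations, in either direction (excess or deficit). The
#' baseline mean and SD are computed across ALL sites of the supplied
#' tracks (pass every autosome's track through `baseline` for a
#' genome-wide baseline). Runs of the same direction separated by at
#' most `gap_sites` sub-threshold sites are merged.
#'
#' @param track `data.frame(chrom, position_bp, proportion)` from
#'   [ancestry_proportion()] (rows from several chromosomes allowed).
#' @param threshold_sd threshold in SD units; see [lad_threshold()].
#' @param baseline optional `data.frame` like `track` (typically all
#'   autosomes row-bound) from which the mean/SD baseline is computed;
#'   defaults to `track` itself.
#' @param gap_sites merge tolerance in sites (default 0).
#' @param ancestry_label label carried into the output.
#' @return A `LADRegionSet` data frame: `chrom`, `start`, `end` (0-based
#'   half-open), `direction` (`"excess"`/`"deficit"`), `n_sites`,
#'   `peak_proportion`, `peak_z`, `ancestry`; attributes
#'   `baseline_mean`, `baseline_sd`. A constant track (zero SD) yields
#'   an empty set with a warning.
#' @export
lad_scan <- function(track, threshold_sd = lad_threshold("strict"),
                     baseline = NULL, gap_sites = 0,
                     ancestry_label = NA_character_) {
  if (is.null(baseline)) baseline <- track
  m_bar <- mean(baseline$proportion)
  sigma <- sd(baseline$proportion)
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), direction = character(0),
                      n_sites = integer(0), peak_proportion = numeric(0),
                      peak_z = numeric(0), ancestry = character(0))
  class(empty) <- c("LADRegionSet", "data.frame")
  attr(empty, "baseline_mean") <- m_bar
  attr(empty, "baseline_sd") <- sigma
  if (is.na(sigma) || sigma == 0) {
    warning("degenerate baseline: zero SD across sites; no regions")
    return(empty)
  }
  z_all <- (track$proportion - m_bar) / sigma
  out <- list()
  for (ch in unique(track$chrom)) {
    rows <- which(track$chrom == ch)
    o <- rows[order(track$position_bp[rows])]
    z <- z_all[o]
    pos <- track$position_bp[o]
    prop <- track$proportion[o]
    state <- ifelse(z > threshold_sd, 1L, ifelse(z < -threshold_sd, -1L, 0L))
    runs <- find_runs(state, gap_sites)
    for (r in runs) {
      zz <- z[r$idx]
      pk <- r$idx[which.max(abs(zz))]
      out[[length(out) + 1L]] <-
        data.frame(chrom = ch,
                   start = pos[r$idx[1]] - 1,
                   end = pos[r$idx[length(r$idx)]],
                   direction = if (r$dir > 0) "excess" else "deficit",
                   n_sites = length(r$idx),
                   peak_proportion = prop[pk],
                   peak_z = z[pk])
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res$ancestry <- ancestry_label
  attr(res, "baseline_mean") <- m_bar
  attr(res, "baseline_sd") <- sigma
  class(res) <- c("LADRegionSet", "data.frame")
  res
}

# maximal runs of constant nonzero state, merging same-direction runs
# separated by <= gap sites of zero state
find_runs <- function(state, gap = 0) {
  runs <- list()
  n <- length(state)
  i <- 1L
  while (i <= n) {
    if (state[i] == 0L) { i <- i + 1L; next }
    dir <- state[i]
    idx <- i
    j <- i + 1L
    zeros <- 0L
    pending <- integer(0)
    while (j <= n) {
      if (state[j] == dir) {
        idx <- c(idx, pending, j)
        pending <- integer(0)
        zeros <- 0L
      } else if (state[j] == 0L && zeros < gap) {
        zeros <- zeros + 1L
        pending <- c(pending, j)
      } else break
      j <- j + 1L
    }
    runs[[length(runs) + 1L]] <- list(dir = dir, idx = idx)
    i <- max(idx) + 1L
  }
  runs
}

#' Overlap LAD regions with selection peaks
#'
#' Interval intersection of deviated-ancestry regions with selection
#' peaks; each overlapping pair is a post-admixture selection candidate,
#' reported with its ancestry label, deviation direction and the peak's
#' method tag.
#'
#' @param lad a `LADRegionSet` from [lad_scan()].
#' @param peaks a `PeakSet` from [call_peaks()].
#' @return data frame with one row per (LAD region, peak) overlap:
#'   coordinates, `ancestry`, `direction`, `peak_z`, `method`,
#'   `overlap_bp`.
#' @export
lad_peak_overlap <- function(lad, peaks) {
  empty <- data.frame(chrom = character(0), lad_start = numeric(0),
                      lad_end = numeric(0), peak_start = numeric(0),
                      peak_end = numeric(0), ancestry = character(0),
                      direction = character(0), peak_z = numeric(0),
                      method = character(0), overlap_bp = numeric(0))
  if (nrow(lad) == 0 || nrow(peaks) == 0) return(empty)
  ov <- overlap_peaks(lad, peaks)  # lad as "peaks", peaks as regions
  if (nrow(ov) == 0) return(empty)
  data.frame(chrom = ov$chrom,
             lad_start = ov$peak_start, lad_end = ov$peak_end,
             peak_start = ov$region_start, peak_end = ov$region_end,
             ancestry = lad$ancestry[ov$peak],
             direction = lad$direction[ov$peak],
             peak_z = lad$peak_z[ov$peak],
             method = peaks$method[ov$region],
             overlap_bp = ov$overlap_bp)
}
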