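#' Peak-calling configuration
#'
#' The classification rule for candidate selection regions: a SNP is a
#' candidate if its standardized score reaches the empirical
#' `primary_quantile` of the genome-wide track, and it is confirmed if
#' the `window_bp` window centred on it contains at least `min_support`
#' ADDITIONAL variants reaching the `support_quantile`. Confirmed
#' candidates' windows are merged into peaks. Note the support quantile
#' is higher than the primary one, exactly as the rule is stated.
#'
#' @param primary_quantile empirical quantile for candidate SNPs
#'   (default 0.9999).
#' @param support_quantile empirical quantile for supporting SNPs
#'   (default 0.99995).
#' @param window_bp window width centred on the candidate (default 1 Mb).
#' @param min_support minimum supporting SNPs in the window (default 10).
#' @param score_side `"upper"` uses the signed score (top tail, the
#'   default); `"two_sided"` ranks `|score|`.
#' @param count_self count the candidate itself towards the support
#'   (default `FALSE`: the stricter "additional variants" reading).
#' @return a `PeakCallingConfig` list.
#' @export
peak_calling_config <- function(primary_quantile = 0.9999,
                                support_quantile = 0.99995,
                                window_bp = 1e6, min_support = 10,
                                score_side = c("upper", "two_sided"),
                                count_self = FALSE) {
  stopifnot(primary_quantile > 0, primary_quantile < 1,
            support_quantile > 0, support_quantile < 1,
            window_bp > 0, min_support >= 0)
  structure(list(primary_quantile = primary_quantile,
                 support_quantile = support_quantile,
                 window_bp = window_bp,
                 min_support = as.integer(min_support),
                 score_side = match.arg(score_side),
                 count_self = isTRUE(count_self)),
            class = "PeakCallingConfig")
}

#' Call selection peaks from a standardized score track
#'
#' Thresholds are type-7 empirical quantiles of the standardized scores
#' over all defined test sites genome-wide. Candidates at or above the
#' primary threshold are confirmed when their centred window holds at
#' least `min_support` other SNPs at or above the support threshold;
#' confirmed candidates' windows are merged (union of overlapping
#' windows, per chromosome) and each merged peak reports its
#' maximum-scoring SNP as the summit.
#'
#' @param track a `ScoreTrack` with `standardized` scores (rows from
#'   several chromosomes may be bound together).
#' @param config a [peak_calling_config()].
#' @return A `PeakSet` data frame: `chrom`, `start`, `end` (0-based
#'   half-open), `summit_pos`, `summit_score`, `n_support`, `method`.
#'   Empty tracks yield an empty `PeakSet`.
#' @export
call_peaks <- function(track, config = peak_calling_config()) {
  stopifnot(inherits(config, "PeakCallingConfig"))
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), summit_pos = numeric(0),
                      summit_score = numeric(0), n_support = integer(0),
                      method = character(0))
  class(empty) <- c("PeakSet", "data.frame")
  if (nrow(track) == 0) return(empty)
  score <- track$standardized
  if (config$score_side == "two_sided") score <- abs(score)
  defined <- !is.na(score)
  n_def <- sum(defined)
  if (n_def == 0) return(empty)
  if (n_def < 1 / (1 - config$primary_quantile))
    warning(sprintf(paste("only %d defined sites for a %.5f quantile;",
                          "thresholds are unstable"),
                    n_def, config$primary_quantile))
  thr <- quantile(score[defined],
                  c(config$primary_quantile, config$support_quantile),
                  type = 7, names = FALSE)
  half <- config$window_bp / 2
  method <- attr(track, "method") %||% "score"
  peaks_by_chrom <- lapply(split(seq_len(nrow(track)), track$chrom),
                           function(rows) {
    pos <- track$position_bp[rows]
    s <- score[rows]
    o <- order(pos)
    pos <- pos[o]; s <- s[o]
    ok <- !is.na(s)
    sup_pos <- pos[ok & s >= thr[2]]
    cand <- which(ok & s >= thr[1])
    if (length(cand) == 0) return(NULL)
    n_sup <- vapply(cand, function(i) {
      inwin <- sum(sup_pos >= pos[i] - half & sup_pos <= pos[i] + half)
      if (!config$count_self && s[i] >= thr[2]) inwin <- inwin - 1L
      inwin
    }, numeric(1))
    confirmed <- cand[n_sup >= config$min_support]
    if (length(confirmed) == 0) return(NULL)
    ir <- IRanges::reduce(IRanges::IRanges(
      start = pmax(0, round(pos[confirmed] - half)),
      end = round(pos[confirmed] + half) - 1L))  # 1-based closed for IRanges
    out <- data.frame(chrom = track$chrom[rows[1]],
                      start = IRanges::start(ir),
                      end = IRanges::end(ir) + 1L)
    out$summit_pos <- NA_real_
    out$summit_score <- NA_real_
    out$n_support <- NA_integer_
    for (k in seq_len(nrow(out))) {
      inpk <- ok & pos > out$start[k] & pos <= out$end[k]
      sm <- which.max(ifelse(inpk, s, -Inf))
      out$summit_pos[k] <- pos[sm]
      out$summit_score[k] <- s[sm]
      out$n_support[k] <- sum(inpk & s >= thr[2])
    }
    out
  })
  peaks <- do.call(rbind, peaks_by_chrom)
  if (is.null(peaks)) return(empty)
  rownames(peaks) <- NULL
  peaks$method <- method
  attr(peaks, "thresholds") <- c(primary = thr[1], support = thr[2])
  class(peaks) <- c("PeakSet", "data.frame")
  peaks
}

#' Overlap peaks with a set of genomic regions
#'
#' Half-open interval intersection; every (peak, region) pair with an
#' intersection of at least 1 bp is reported.
#'
#' @param peaks a `PeakSet` (or any `data.frame(chrom, start, end)`).
#' @param regions `data.frame(chrom, start, end, ...)`, same chromosome
#'   naming.
#' @return data frame with one row per overlapping pair: peak and region
#'   coordinates plus the intersection `overlap_start`, `overlap_end`,
#'   `overlap_bp`. Empty inputs give an empty report.
#' @export
overlap_peaks <- function(peaks, regions) {
  empty <- data.frame(peak = integer(0), region = integer(0),
                      chrom = character(0),
                      peak_start = numeric(0), peak_end = numeric(0),
                      region_start = numeric(0), region_end = numeric(0),
                      overlap_start = numeric(0), overlap_end = numeric(0),
                      overlap_bp = numeric(0))
  if (nrow(peaks) == 0 || nrow(regions) == 0) return(empty)
  gp <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1,
                                                peaks$end))
  gr <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start + 1,
                                                regions$end))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gp, gr, minoverlap = 1L))
  if (length(hits) == 0) return(empty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov_start <- pmax(peaks$start[qi], regions$start[si])
  ov_end <- pmin(peaks$end[qi], regions$end[si])
  data.frame(peak = qi, region = si,
             chrom = peaks$chrom[qi],
             peak_start = peaks$start[qi], peak_end = peaks$end[qi],
             region_start = regions$start[si],
             region_end = regions$end[si],
             overlap_start = ov_start, overlap_end = ov_end,
             overlap_bp = ov_end - ov_start)
}
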