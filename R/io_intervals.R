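#' Read a BED file of intervals
#'
#' Standard 0-based half-open BED: chrom, start, end (extra columns kept
#' as `name`, ...). Used for centromere/exclusion masks and for the true
#' selected locus emitted by the simulator.
#'
#' @param path file path.
#' @return `data.frame(chrom, start, end, ...)`.
#' @export
read_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(tab)[1:3] <- c("chrom", "start", "end")
  if (ncol(tab) >= 4L) names(tab)[4L] <- "name"
  tab$chrom <- as.character(tab$chrom)
  tab
}

#' Write intervals as BED
#'
#' @param intervals `data.frame` with columns `chrom`, `start`, `end` and
#'   optionally `name` (0-based half-open coordinates).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "name"), names(intervals))
  tab <- intervals[, cols, drop = FALSE]
  tab$start <- format(round(tab$start), scientific = FALSE, trim = TRUE)
  tab$end <- format(round(tab$end), scientific = FALSE, trim = TRUE)
  utils::write.table(tab, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a score track as TSV
#'
#' Shared column layout for SDS and XP-EHH tracks: chrom, pos, raw,
#' standardized, pvalue (plus `neglog10_p` for Manhattan plotting).
#'
#' @param track a `ScoreTrack` data frame (see [xpehh()], [sds_scan()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_track <- function(track, path) {
  out <- data.frame(chrom = track$chrom,
                    pos = format(round(track$position_bp),
                                 scientific = FALSE, trim = TRUE),
                    raw = sprintf("%.6g", track$raw),
                    standardized = sprintf("%.6g", track$standardized),
                    pvalue = sprintf("%.6g", track$pvalue),
                    neglog10_p = sprintf("%.6g", -log10(track$pvalue)),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
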