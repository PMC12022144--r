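#' Genetic map with bp-to-cM interpolation
#'
#' Builds an interpolator from a monotone table of (bp, cM) map points.
#' Queries between points are linearly interpolated; queries beyond either
#' end are extrapolated with the terminal cM/Mb slope (or with the overall
#' mean rate when the map has a single point).
#'
#' @param positions_bp physical positions of the map points (increasing).
#' @param positions_cM genetic positions (non-decreasing).
#' @param chrom chromosome label.
#' @return An object of class `GeneticMap`; call it via [interpolate_cM()].
#' @export
genetic_map <- function(positions_bp, positions_cM, chrom = "1") {
  if (length(positions_bp) != length(positions_cM) || length(positions_bp) < 1)
    stop("map needs matching bp and cM vectors")
  o <- order(positions_bp)
  positions_bp <- positions_bp[o]
  positions_cM <- positions_cM[o]
  if (any(diff(positions_bp) <= 0))
    stop("non-monotone map: duplicated bp positions")
  if (any(diff(positions_cM) < 0))
    stop("non-monotone map: cM must be non-decreasing in bp")
  structure(list(bp = as.numeric(positions_bp),
                 cM = as.numeric(positions_cM),
                 chrom = as.character(chrom)),
            class = "GeneticMap")
}

#' Interpolate genetic positions
#'
#' @param map a [genetic_map()].
#' @param query_bp physical positions to convert.
#' @return numeric vector of cM positions, non-decreasing in `query_bp`.
#' @export
interpolate_cM <- function(map, query_bp) {
  stopifnot(inherits(map, "GeneticMap"))
  bp <- map$bp; cM <- map$cM
  n <- length(bp)
  if (n == 1L) {  # degenerate map point: assume 1 cM/Mb through it
    return(cM[1] + (query_bp - bp[1]) * 1e-6)
  }
  slope_lo <- (cM[2] - cM[1]) / (bp[2] - bp[1])
  slope_hi <- (cM[n] - cM[n - 1]) / (bp[n] - bp[n - 1])
  out <- stats::approx(bp, cM, xout = query_bp, rule = 2)$y
  lo <- query_bp < bp[1]
  hi <- query_bp > bp[n]
  out[lo] <- cM[1] + (query_bp[lo] - bp[1]) * slope_lo
  out[hi] <- cM[n] + (query_bp[hi] - bp[n]) * slope_hi
  out
}

#' Read a PLINK-style genetic map
#'
#' Accepts a 4-column PLINK `.map` layout (chrom, id, cM, bp) or a
#' HapMap-style 3-column layout (chrom/position/rate-free: chrom, bp, cM).
#' Columns are detected by header names when present, otherwise the
#' 4-column PLINK order is assumed.
#'
#' @param path file path.
#' @return a [genetic_map()].
#' @export
read_genetic_map <- function(path) {
  first <- strsplit(trimws(readLines(path, n = 1L)), "[ \t]+")[[1]]
  tail2 <- suppressWarnings(as.numeric(first[max(1, length(first) - 1):length(first)]))
  has_header <- anyNA(tail2)
  tab <- utils::read.table(path, header = has_header,
                           stringsAsFactors = FALSE)
  if (has_header) {
    nm <- tolower(names(tab))
    bp_col <- grep("bp|pos|position", nm)[1]
    cm_col <- grep("cm|genetic|map", nm)[1]
    ch_col <- grep("chr", nm)[1]
    if (is.na(bp_col) || is.na(cm_col))
      stop("cannot identify bp/cM columns in map header")
    chrom <- if (!is.na(ch_col)) as.character(tab[1, ch_col]) else "1"
    genetic_map(tab[[bp_col]], tab[[cm_col]], chrom = chrom)
  } else {
    if (ncol(tab) < 4L) stop("headerless map must have 4 PLINK columns")
    genetic_map(tab[[4]], tab[[3]], chrom = as.character(tab[1, 1]))
  }
}

#' Write a PLINK-style genetic map
#'
#' Writes the 4-column PLINK `.map` layout: chrom, snp id, cM, bp.
#'
#' @param map a [genetic_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genetic_map <- function(map, path) {
  stopifnot(inherits(map, "GeneticMap"))
  tab <- data.frame(chrom = map$chrom,
                    id = sprintf("site%d", seq_along(map$bp)),
                    cM = map$cM,
                    bp = round(map$bp))
  utils::write.table(tab, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
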