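#' Read an RFmix-style local ancestry table
#'
#' Parses the `.msp.tsv` layout: a first comment line with ancestry codes
#' (`#Subpopulation order/codes: X=0 Y=1 ...`), a header row, then one row
#' per window with chrom, physical start/end, genetic start/end, number of
#' SNPs, and one integer ancestry column per haplotype. Windows are
#' half-open `[spos, epos)` and must tile the covered region without gaps
#' or overlaps. Assignments are expanded onto `positions_bp`: a site takes
#' the label of its containing window.
#'
#' @param path file path.
#' @param positions_bp site positions to expand onto (default: window
#'   start positions, one site per window).
#' @param sample_ids optional diploid sample order; haplotype columns are
#'   realigned to `<id>.0`, `<id>.1` per sample.
#' @return an [ancestry_matrix()].
#' @export
read_ancestry_table <- function(path, positions_bp = NULL,
                                sample_ids = NULL) {
  lines <- readLines(path)
  if (!grepl("^#Subpopulation", lines[1]))
    stop("missing '#Subpopulation order/codes' header line")
  codes_part <- sub("^#Subpopulation order/codes:\\s*", "", lines[1])
  pairs <- strsplit(strsplit(trimws(codes_part), "[\t ]+")[[1]], "=")
  labels <- vapply(pairs, `[`, "", 1L)
  codes <- as.integer(vapply(pairs, `[`, "", 2L))
  labels <- labels[order(codes)]

  header <- strsplit(sub("^#", "", lines[2]), "\t")[[1]]
  tab <- utils::read.table(text = lines[-(1:2)], sep = "\t",
                           stringsAsFactors = FALSE)
  names(tab) <- header
  hap_cols <- 7:ncol(tab)
  spos <- as.numeric(tab[[2]])
  epos <- as.numeric(tab[[3]])
  o <- order(spos)
  tab <- tab[o, , drop = FALSE]; spos <- spos[o]; epos <- epos[o]
  if (any(epos <= spos))
    stop("degenerate ancestry window (epos <= spos) at rows: ",
         paste(which(epos <= spos), collapse = ", "))
  gaps <- which(abs(spos[-1] - epos[-length(epos)]) > 0)
  if (length(gaps) > 0)
    stop("ancestry windows have gaps/overlaps after rows: ",
         paste(gaps, collapse = ", "))
  M <- unname(t(as.matrix(tab[, hap_cols, drop = FALSE])))
  if (any(!M %in% (seq_along(labels) - 1L)))
    stop("unknown ancestry code in table (codes must be 0..K-1)")

  hap_names <- header[hap_cols]
  if (!is.null(sample_ids)) {
    want <- as.vector(rbind(paste0(sample_ids, ".0"),
                            paste0(sample_ids, ".1")))
    idx <- match(want, hap_names)
    if (anyNA(idx))
      stop("ancestry table is missing haplotype columns: ",
           paste(want[is.na(idx)], collapse = ", "))
    M <- M[idx, , drop = FALSE]
  }
  if (is.null(positions_bp)) {
    out <- M
    positions_bp <- spos
  } else {
    win <- findInterval(positions_bp, spos)
    if (any(win == 0) || any(positions_bp >= epos[length(epos)]))
      stop("site positions outside the ancestry windows")
    out <- M[, win, drop = FALSE]
  }
  ancestry_matrix(out, positions_bp, labels,
                  chrom = as.character(tab[1, 1]))
}

#' Write an RFmix-style local ancestry table
#'
#' Collapses consecutive sites with identical assignments across all
#' haplotypes into windows and writes the `.msp.tsv` layout read by
#' [read_ancestry_table()]. Window boundaries sit at the first site of
#' each run; the final window is closed one bp past the last site.
#'
#' @param am an [ancestry_matrix()].
#' @param path output path.
#' @param sample_ids diploid sample ids (two haplotype columns each);
#'   defaults to `ind001...`.
#' @param positions_cM optional genetic positions for the sgpos/egpos
#'   columns (default: bp * 1e-6).
#' @return `path`, invisibly.
#' @export
write_ancestry_table <- function(am, path, sample_ids = NULL,
                                 positions_cM = NULL) {
  stopifnot(inherits(am, "AncestryMatrix"))
  M <- am$codes
  pos <- am$positions_bp
  if (is.null(positions_cM)) positions_cM <- pos * 1e-6
  n_hap <- nrow(M)
  if (is.null(sample_ids))
    sample_ids <- sprintf("ind%03d", seq_len(ceiling(n_hap / 2)))
  hap_names <- as.vector(rbind(paste0(sample_ids, ".0"),
                               paste0(sample_ids, ".1")))[seq_len(n_hap)]
  # run-length encode identical consecutive columns
  m <- ncol(M)
  new_run <- c(TRUE, vapply(seq_len(m - 1L), function(j)
    any(M[, j + 1L] != M[, j]), logical(1)))
  starts <- which(new_run)
  ends <- c(starts[-1L] - 1L, m)
  spos <- round(pos[starts])
  epos <- c(spos[-1L], round(pos[m]) + 1L)
  rows <- cbind(am$chrom, spos, epos,
                format(positions_cM[starts], digits = 8),
                format(c(positions_cM[starts][-1L],
                         positions_cM[m]), digits = 8),
                ends - starts + 1L,
                t(M[, starts, drop = FALSE]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#Subpopulation order/codes: ",
                    paste(am$labels, seq_along(am$labels) - 1L,
                          sep = "=", collapse = "\t")), con)
  writeLines(paste(c("#chm", "spos", "epos", "sgpos", "egpos", "n snps",
                     hap_names), collapse = "\t"), con)
  writeLines(apply(rows, 1L, paste, collapse = "\t"), con)
  invisible(path)
}
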