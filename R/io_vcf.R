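#' Read a phased VCF into a polarized panel
#'
#' Reads a VCF with fully phased diploid genotypes, keeps biallelic SNPs
#' only (indels, multiallelic and structural records are dropped), and
#' polarizes alleles so that 1 = derived. The ancestral allele comes from
#' the `INFO/AA` tag (`ancestral_source = "AA"`) or from an ancestral
#' FASTA file path; sites whose ancestral state is missing or matches
#' neither REF nor ALT are dropped and counted in the attached log, as
#' are sites with any missing genotype.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param ancestral_source `"AA"` or the path to an ancestral FASTA whose
#'   first record covers the chromosome (1-based base per position).
#' @param map optional [genetic_map()] used for cM positions; without it a
#'   uniform 1 cM/Mb map is assumed (with a warning).
#' @return list with `panel` (a [phased_panel()]), `sites`
#'   (a [site_table()]) and `log` (dropped-site counts).
#' @export
read_phased_vcf <- function(path, ancestral_source = "AA", map = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  n_total <- length(ref)
  snp <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_not_snp <- sum(!snp)

  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = n_total)
  gt <- gt[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]
  ref <- ref[snp]; alt <- alt[snp]
  pos <- as.numeric(fix[, "POS"])
  chrom <- if (nrow(fix) > 0) fix[1, "CHROM"] else "1"

  unphased <- which(matrix(grepl("/", gt), nrow = nrow(gt)), arr.ind = TRUE)
  if (nrow(unphased) > 0) {
    stop(sprintf("unphased genotype at site %s:%s for sample %s",
                 chrom, pos[unphased[1, 1]],
                 colnames(gt)[unphased[1, 2]]))
  }
  miss <- is.na(gt) | gt %in% c(".|.", ".")
  drop_missing <- rowSums(miss) > 0
  n_missing <- sum(drop_missing)

  # ancestral allele per site
  if (identical(ancestral_source, "AA")) {
    info <- fix[, "INFO"]
    aa <- rep(NA_character_, length(info))
    has <- grepl("AA=", info)
    aa[has] <- toupper(sub("AA=", "", regmatches(info, regexpr("AA=[A-Za-z.]+", info))))
  } else {
    if (!requireNamespace("Biostrings", quietly = TRUE))
      stop("Biostrings is required to read an ancestral FASTA")
    fa <- Biostrings::readDNAStringSet(ancestral_source)
    seqs <- as.character(fa[[1]])
    aa <- toupper(substring(seqs, pos, pos))
  }
  aa_ok <- !is.na(aa) & (aa == ref | aa == alt)
  n_bad_aa <- sum(!aa_ok & !drop_missing)

  keep <- aa_ok & !drop_missing
  if (sum(keep) == 0)
    stop("no usable polarized biallelic SNPs in VCF")
  gt <- gt[keep, , drop = FALSE]
  pos <- pos[keep]; ref <- ref[keep]; alt <- alt[keep]; aa <- aa[keep]

  # genotype strings -> two haplotype rows per sample
  a1 <- as.integer(substr(gt, 1L, 1L))
  a2 <- as.integer(substr(gt, 3L, 3L))
  m <- nrow(gt); ns <- ncol(gt)
  H <- matrix(0L, nrow = 2L * ns, ncol = m)
  H[seq(1L, 2L * ns, by = 2L), ] <- t(matrix(a1, nrow = m))
  H[seq(2L, 2L * ns, by = 2L), ] <- t(matrix(a2, nrow = m))

  flip <- aa == alt  # ALT is ancestral: invert codes so 1 = derived
  if (any(flip))
    H[, flip] <- 1L - H[, flip]
  derived <- ifelse(flip, ref, alt)

  o <- order(pos)
  pos <- pos[o]; H <- H[, o, drop = FALSE]
  aa <- aa[o]; derived <- derived[o]
  cm <- if (!is.null(map)) interpolate_cM(map, pos) else NULL
  panel <- phased_panel(H, pos, positions_cM = cm, chrom = chrom,
                        sample_ids = colnames(gt))
  attr(panel, "ancestral_allele") <- aa
  attr(panel, "derived_allele") <- derived
  sites <- site_table(panel)
  list(panel = panel, sites = sites,
       log = list(n_records = n_total, n_not_biallelic_snp = n_not_snp,
                  n_missing_genotype = n_missing,
                  n_unresolved_ancestral = n_bad_aa,
                  n_kept = ncol(panel$haplotypes)))
}

#' Write a panel as a phased VCF
#'
#' Emits phased `GT` fields with the `|` separator and the ancestral
#' allele in `INFO/AA`. The panel's 0/1 codes are written with the
#' ancestral allele as REF, so polarization round-trips. Fractional
#' simulator positions are rounded up to distinct integer coordinates.
#'
#' @param panel a [phased_panel()].
#' @param path output path.
#' @param sites optional [site_table()] supplying allele letters.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(panel, path, sites = NULL) {
  stopifnot(inherits(panel, "PhasedPanel"))
  if (is.null(sites)) sites <- site_table(panel)
  pos <- ceiling(panel$positions_bp)
  pos[pos < 1] <- 1
  while (any(dup <- duplicated(pos)))  # bump collisions from rounding
    pos[dup] <- pos[dup] + 1L
  H <- panel$haplotypes
  ns <- nrow(H) %/% 2L
  odd <- seq(1L, nrow(H), by = 2L)
  gt <- matrix(paste(H[odd, , drop = FALSE], H[odd + 1L, , drop = FALSE],
                     sep = "|"),
               nrow = ns)
  lines <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", panel$sample_ids), collapse = "\t"))
  body <- cbind(panel$chrom, format(pos, scientific = FALSE, trim = TRUE),
                sprintf("site%d", seq_along(pos)),
                sites$ancestral_allele, sites$derived_allele, ".", "PASS",
                paste0("AA=", sites$ancestral_allele), "GT",
                t(gt))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}
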