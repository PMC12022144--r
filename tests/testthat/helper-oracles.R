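# Independent brute-force oracles and small fixture builders.

# random phased panel: n haplotypes (even), m sites, random 0/1 alleles
# (each site forced polymorphic), uniform-ish positions
random_panel <- function(n, m, seed) {
  set.seed(seed)
  H <- matrix(rbinom(n * m, 1L, runif(1, 0.2, 0.8)), nrow = n)
  for (j in seq_len(m)) {            # keep every site segregating
    if (all(H[, j] == H[1, j])) H[sample(n, 1), j] <- 1L - H[1, j]
  }
  pos <- sort(sample.int(1e6, m))
  suppressWarnings(phased_panel(H, pos))
}

# all-pairs EHH oracle: for each extension j (0 = core only, value 1 by
# convention), count identical haplotype pairs over sites core..core+dir*j
ehh_oracle <- function(H, core, dir) {
  n <- nrow(H)
  m <- ncol(H)
  len <- if (dir > 0) m - core + 1 else core
  out <- numeric(len)
  out[1] <- 1
  if (len > 1) {
    for (j in 2:len) {
      cols <- core + dir * (0:(j - 1))
      key <- apply(H[, cols, drop = FALSE], 1, paste, collapse = "")
      same <- 0
      for (a in 1:(n - 1)) for (b in (a + 1):n)
        same <- same + (key[a] == key[b])
      out[j] <- same / choose(n, 2)
    }
  }
  out
}

# singleton-distance generator under the exponential tip model
model_distances <- function(n, m_anc, m_der, f, seed, boundary = Inf) {
  set.seed(seed)
  g <- rbinom(n, 2, f)
  rate <- (2 - g) / m_anc + g / m_der
  l <- rexp(n, rate)
  r <- rexp(n, rate)
  data.frame(individual = seq_len(n), genotype = g,
             left_distance = pmin(l, boundary),
             right_distance = pmin(r, boundary),
             left_censored = l > boundary,
             right_censored = r > boundary)
}

# iid standard-normal score track with optional planted blocks
normal_track <- function(n, seed, spacing_bp = 1000, chrom = "1") {
  set.seed(seed)
  out <- data.frame(chrom = rep(chrom, n),
                    position_bp = seq_len(n) * spacing_bp,
                    site = seq_len(n),
                    raw = rnorm(n),
                    standardized = rep(NA_real_, n),
                    pvalue = rep(NA_real_, n))
  out$standardized <- out$raw
  attr(out, "method") <- "TEST"
  class(out) <- c("ScoreTrack", "data.frame")
  out
}

plant_block <- function(track, start_bp, end_bp, score) {
  i <- track$position_bp >= start_bp & track$position_bp <= end_bp
  track$standardized[i] <- score
  track
}

# tiny phased VCF written by hand (for reader edge cases)
write_toy_vcf <- function(path, rows, samples = c("s1", "s2")) {
  head <- c("##fileformat=VCFv4.2",
            "##INFO=<ID=AA,Number=1,Type=String,Description=\"AA\">",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
            paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(head, rows), path)
  path
}

toy_vcf_row <- function(pos, ref, alt, aa, gts, chrom = "1") {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS",
          paste0("AA=", aa), "GT", gts), collapse = "\t")
}
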