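test_that("phased VCF reading polarizes against the ancestral allele", {
  # REF is ancestral everywhere -> ALT must come back as derived (code 1)
  f <- tempfile(fileext = ".vcf")
  write_toy_vcf(f, c(
    toy_vcf_row(100, "A", "G", "A", c("0|1", "0|0")),
    toy_vcf_row(200, "C", "T", "C", c("1|1", "0|1"))))
  res <- suppressWarnings(read_phased_vcf(f))
  expect_equal(res$panel$positions_bp, c(100, 200))
  expect_equal(res$panel$haplotypes[, 1], c(0L, 1L, 0L, 0L))
  expect_equal(res$sites$derived_allele, c("G", "T"))

  # AA equal to ALT -> codes flip and f maps to 1 - f
  f2 <- tempfile(fileext = ".vcf")
  write_toy_vcf(f2, c(
    toy_vcf_row(100, "A", "G", "G", c("0|1", "0|0")),
    toy_vcf_row(200, "C", "T", "C", c("1|1", "0|1"))))
  res2 <- suppressWarnings(read_phased_vcf(f2))
  expect_equal(res2$panel$haplotypes[, 1], 1L - res$panel$haplotypes[, 1])
  expect_equal(res2$sites$derived_freq[1], 1 - res$sites$derived_freq[1])
  expect_equal(res2$sites$derived_allele[1], "A")
})

test_that("unphased genotypes abort with site and sample named", {
  f <- tempfile(fileext = ".vcf")
  write_toy_vcf(f, toy_vcf_row(100, "A", "G", "A", c("0/1", "0|0")))
  expect_error(suppressWarnings(read_phased_vcf(f)), "unphased.*100.*s1")
})

test_that("sites without usable ancestral state are dropped and logged", {
  f <- tempfile(fileext = ".vcf")
  write_toy_vcf(f, c(
    toy_vcf_row(100, "A", "G", "A", c("0|1", "0|0")),
    toy_vcf_row(200, "C", "T", ".", c("1|1", "0|1")),   # unknown AA
    toy_vcf_row(300, "C", "T", "G", c("0|1", "0|1"))))  # AA matches neither
  res <- suppressWarnings(read_phased_vcf(f))
  expect_equal(nrow(res$sites), 1L)
  expect_equal(res$log$n_unresolved_ancestral, 2L)
})

test_that("an ancestral FASTA can replace INFO/AA", {
  skip_if_not_installed("Biostrings")
  f <- tempfile(fileext = ".vcf")
  write_toy_vcf(f, c(
    toy_vcf_row(3, "A", "G", ".", c("0|1", "0|0")),
    toy_vcf_row(7, "C", "T", ".", c("1|1", "0|1"))))
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", "NNANNNTNNN"), fa)  # pos 3 = A (REF), pos 7 = T (ALT)
  res <- suppressWarnings(read_phased_vcf(f, ancestral_source = fa))
  expect_equal(res$panel$haplotypes[, 1], c(0L, 1L, 0L, 0L))  # A ancestral
  expect_equal(res$panel$haplotypes[, 2], c(0L, 0L, 1L, 0L))  # T ancestral: flip
})

test_that("panels round-trip through the phased VCF writer", {
  sim <- simulate_panel(sweep_sim_config(n_diploids = 8, seq_len_bp = 1e5,
                                         mu = 1e-6, rho = 1e-7, Ne = 40,
                                         s = 0, seed = 31))
  f <- tempfile(fileext = ".vcf")
  write_phased_vcf(sim$panel, f, sim$sites)
  back <- suppressWarnings(read_phased_vcf(f))
  expect_equal(back$panel$haplotypes, sim$panel$haplotypes,
               ignore_attr = TRUE)
  expect_equal(back$sites$derived_count, sim$sites$derived_count)
  expect_equal(back$sites$is_singleton, sim$sites$is_singleton)
  expect_equal(back$sites$singleton_owner, sim$sites$singleton_owner)
})

test_that("a lone observed ALT is flagged as a singleton with its owner", {
  f <- tempfile(fileext = ".vcf")
  rows <- vapply(1:10, function(i)
    toy_vcf_row(i * 100, "A", "G", "A",
                if (i == 4) c("0|0", "1|0", "0|0")
                else c("0|1", "0|1", "1|1")), character(1))
  write_toy_vcf(f, rows, samples = c("s1", "s2", "s3"))
  res <- suppressWarnings(read_phased_vcf(f))
  expect_equal(sum(res$sites$is_singleton), 1L)
  expect_equal(res$sites$singleton_owner[res$sites$is_singleton], 2L)
  expect_equal(sum(res$sites$derived_count == 1L),
               sum(res$sites$is_singleton))
})

test_that("test-SNP selection applies MAF, genotype-class and region filters", {
  # 20 diploids (40 haplotypes); columns with controlled structure
  col <- function(g) as.vector(rbind(as.integer(g >= 1), as.integer(g == 2)))
  H <- cbind(
    col(c(rep(0, 6), rep(1, 8), rep(2, 6))),      # f = 0.5, 3 classes -> keep
    col(c(rep(2, 19), 1)),                        # f = 39/40 > 0.95 -> MAF drop
    col(c(rep(0, 14), rep(1, 6))),                # f = 0.15, no hom-derived
    col(c(rep(0, 19), 1)),                        # singleton -> never a test SNP
    col(c(rep(0, 10), rep(1, 6), rep(2, 4))))     # f = 0.35, 3 classes -> keep
  panel <- suppressWarnings(phased_panel(H, positions_bp = (1:5) * 1e4))
  st <- site_table(panel)
  idx <- select_test_snps(st, panel)
  expect_equal(idx, c(1L, 5L))
  # excluded interval removes one surviving site
  idx2 <- select_test_snps(st, panel,
                           excluded = data.frame(chrom = "1",
                                                 start = 9000, end = 11000))
  expect_equal(idx2, 5L)
  # idempotent and order-independent
  o <- rev(seq_len(nrow(st)))
  expect_equal(sort(select_test_snps(st[o, ], panel)), idx)
  expect_warning(
    select_test_snps(st, panel,
                     excluded = data.frame(chrom = "1", start = 0, end = 1e5)),
    "no sites")
})

test_that("genetic map interpolation and extrapolation follow the rules", {
  gm <- genetic_map(c(0, 1e6), c(0, 1))
  expect_equal(interpolate_cM(gm, 5e5), 0.5)
  expect_equal(interpolate_cM(gm, 1e6), 1)
  expect_equal(interpolate_cM(gm, 2e6), 2)     # terminal slope 1 cM/Mb
  expect_equal(interpolate_cM(gm, -1e6), -1)
  expect_error(genetic_map(c(0, 1e6), c(1, 0)), "non-monotone")
  expect_error(genetic_map(c(0, 0), c(0, 1)), "non-monotone")
  f <- tempfile(fileext = ".map")
  write_genetic_map(gm, f)
  gm2 <- read_genetic_map(f)
  expect_equal(interpolate_cM(gm2, c(25e4, 75e4)), c(0.25, 0.75))
})

test_that("RFmix-style ancestry tables round-trip and expand correctly", {
  codes <- rbind(c(0L, 0L, 1L), c(1L, 1L, 1L), c(0L, 2L, 2L), c(2L, 2L, 0L))
  am <- ancestry_matrix(codes, positions_bp = c(100, 500, 900),
                        labels = c("AFR", "EUR", "NAF"))
  f <- tempfile(fileext = ".msp.tsv")
  write_ancestry_table(am, f)
  back <- read_ancestry_table(f, positions_bp = c(100, 500, 900))
  expect_identical(back$codes, am$codes)
  expect_identical(back$labels, am$labels)

  # single constant window
  am2 <- ancestry_matrix(matrix(0L, 4, 5), positions_bp = (1:5) * 100,
                         labels = c("A", "B"))
  f2 <- tempfile()
  write_ancestry_table(am2, f2)
  back2 <- read_ancestry_table(f2, positions_bp = (1:5) * 100)
  expect_true(all(back2$codes == 0L))

  # boundary convention: the switch happens exactly at the boundary site
  am3 <- ancestry_matrix(rbind(c(0L, 0L, 1L, 1L), c(0L, 0L, 0L, 0L)),
                         positions_bp = c(100, 200, 300, 400),
                         labels = c("A", "B"))
  f3 <- tempfile()
  write_ancestry_table(am3, f3)
  back3 <- read_ancestry_table(f3, positions_bp = c(100, 200, 300, 400))
  expect_equal(back3$codes[1, ], c(0L, 0L, 1L, 1L))
})

test_that("malformed ancestry tables are rejected", {
  lines <- c("#Subpopulation order/codes: A=0\tB=1",
             paste(c("#chm", "spos", "epos", "sgpos", "egpos", "n snps",
                     "ind001.0", "ind001.1"), collapse = "\t"),
             "1\t0\t100\t0\t0.1\t5\t0\t1",
             "1\t150\t300\t0.15\t0.3\t5\t1\t0")   # gap 100-150
  f <- tempfile()
  writeLines(lines, f)
  expect_error(read_ancestry_table(f), "gaps")
  lines[4] <- "1\t100\t300\t0.15\t0.3\t5\t2\t0"   # unknown code 2
  writeLines(lines, f)
  expect_error(read_ancestry_table(f), "unknown ancestry code")
})

test_that("BED intervals round-trip and flag excluded sites", {
  bed <- data.frame(chrom = "1", start = c(0, 5000), end = c(1000, 8000),
                    name = c("cen", "gap"))
  f <- tempfile(fileext = ".bed")
  write_bed(bed, f)
  back <- read_bed(f)
  expect_equal(back$start, bed$start)
  expect_equal(back$end, bed$end)
  panel <- suppressWarnings(phased_panel(rbind(c(1L,0L,1L), c(0L,1L,0L)),
                                         positions_bp = c(500, 3000, 6000)))
  st <- site_table(panel, excluded = back)
  expect_equal(st$in_excluded_region, c(TRUE, FALSE, TRUE))
})
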