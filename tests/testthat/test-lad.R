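test_that("ancestry proportions count haplotypes per site", {
  codes <- rbind(c(0L, 1L), c(0L, 1L), c(1L, 1L), c(1L, 0L))
  am <- ancestry_matrix(codes, positions_bp = c(100, 200),
                        labels = c("NAF", "EUR"))
  p0 <- ancestry_proportion(am, "NAF")
  expect_equal(p0$proportion, c(0.5, 0.25))
  expect_equal(ancestry_proportion(am, 1L)$proportion, c(0.5, 0.75))
  expect_error(ancestry_proportion(am, "XXX"), "unknown ancestry")
  # proportions over all ancestries sum to one at every site
  total <- Reduce(`+`, lapply(am$labels, function(l)
    ancestry_proportion(am, l)$proportion))
  expect_equal(total, rep(1, 2))
  # degenerate cases: everybody or nobody
  all1 <- ancestry_matrix(matrix(1L, 4, 3), (1:3) * 100, c("A", "B"))
  expect_equal(ancestry_proportion(all1, "B")$proportion, rep(1, 3))
  expect_equal(ancestry_proportion(all1, "A")$proportion, rep(0, 3))
})

test_that("a constant track yields no regions and a warning", {
  trk <- data.frame(chrom = "1", position_bp = (1:50) * 1000,
                    proportion = rep(0.3, 50))
  expect_warning(out <- lad_scan(trk, 3), "degenerate")
  expect_equal(nrow(out), 0L)
})

test_that("a planted deviation block is flagged at both presets", {
  set.seed(5)
  n <- 2000
  block <- 301:360
  # the genomic baseline fluctuates on a sigma = 0.01 scale; the scanned
  # track departs from it only in the planted block, at m + 5 sigma
  baseline <- data.frame(chrom = "1", position_bp = (1:n) * 1e3,
                         proportion = 0.1 + rnorm(n, sd = 0.01))
  trk <- data.frame(chrom = "1", position_bp = (1:n) * 1e3,
                    proportion = replace(rep(0.1, n), block,
                                         mean(baseline$proportion) +
                                           5 * sd(baseline$proportion)))
  for (t in c(lad_threshold("lenient"), lad_threshold("strict"))) {
    out <- lad_scan(trk, t, baseline = baseline, ancestry_label = "NAF")
    expect_equal(nrow(out), 1L)
    expect_equal(out$direction, "excess")
    expect_gte(out$start, 300e3 - 1e3)
    expect_lte(out$end, 361e3)
    expect_gte(abs(out$peak_z), t)
  }
  # deficits are flagged symmetrically
  trk2 <- trk
  trk2$proportion[block] <- 0.1 - 5 * 0.01
  out2 <- lad_scan(trk2, 3)
  expect_equal(out2$direction, "deficit")
})

test_that("threshold presets carry the documented values", {
  expect_equal(lad_threshold("strict"), 4.42)
  expect_equal(lad_threshold("lenient"), 3)
})

test_that("regions nest monotonically in the threshold", {
  set.seed(6)
  n <- 3000
  trk <- data.frame(chrom = "1", position_bp = (1:n) * 1e3,
                    proportion = 0.2 + rnorm(n, sd = 0.02))
  trk$proportion[1000:1040] <- 0.2 + 0.02 * seq(2, 8, length.out = 41)
  lo <- lad_scan(trk, 3)
  hi <- lad_scan(trk, 4.42)
  # every strict region is contained in some lenient region
  for (i in seq_len(nrow(hi))) {
    inside <- any(lo$start <= hi$start[i] & lo$end >= hi$end[i])
    expect_true(inside)
  }
})

test_that("gap merging joins same-direction runs across small dips", {
  m <- rep(0.1, 400)
  z <- c(rep(0.3, 5), 0.1, rep(0.3, 5))       # two runs split by one dip
  trk <- data.frame(chrom = "1", position_bp = (1:411) * 1e3,
                    proportion = c(m, z))
  strict <- lad_scan(trk, 3, gap_sites = 0)
  merged <- lad_scan(trk, 3, gap_sites = 1)
  expect_equal(nrow(strict), 2L)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$n_sites, 11L)
})

test_that("neutral mosaics self-standardize consistently", {
  cfg <- tract_sim_config(n_haplotypes = 100, chrom_len_cM = 100,
                          m = c(0.9, 0.1), g = 30, seed = 8)
  sim <- simulate_tracts(cfg, grid_cM = seq(0, 100, length.out = 2000))
  trk <- ancestry_proportion(sim$ancestry, 1L)
  z <- (trk$proportion - mean(trk$proportion)) / sd(trk$proportion)
  expect_lt(abs(mean(z)), 0.02)
  expect_true(sd(z) >= 0.95 && sd(z) <= 1.05)
})

test_that("LAD-by-peak overlap reports one row per overlapping pair", {
  lad <- data.frame(chrom = "1", start = c(100, 5000), end = c(1000, 6000),
                    direction = c("excess", "deficit"),
                    n_sites = c(10L, 10L), peak_proportion = c(0.3, 0.05),
                    peak_z = c(5, -5), ancestry = "NAF")
  class(lad) <- c("LADRegionSet", "data.frame")
  peaks <- data.frame(chrom = "1", start = c(200, 700), end = c(400, 900),
                      method = "SDS")
  class(peaks) <- c("PeakSet", "data.frame")
  joint <- lad_peak_overlap(lad, peaks)
  expect_equal(nrow(joint), 2L)   # one LAD region spanning two peaks
  expect_equal(joint$ancestry, c("NAF", "NAF"))
  expect_equal(joint$method, c("SDS", "SDS"))
  # identical intervals -> single candidate; disjoint -> empty
  expect_equal(nrow(lad_peak_overlap(lad[1, ],
                                     data.frame(chrom = "1", start = 100,
                                                end = 1000, method = "X"))), 1L)
  expect_equal(nrow(lad_peak_overlap(lad[1, ],
                                     data.frame(chrom = "2", start = 100,
                                                end = 1000, method = "X"))), 0L)
})
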