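test_that("singleton distances are collected per owner with censoring", {
  # 3 diploids, hand-placed singletons around a central test SNP
  # sites: 10k (s, ind2), 40k (s, ind1), 50k (test, f=1/2), 60k (s, ind1),
  #        90k (s, ind3); boundary sites at 1k and 99k
  col <- function(hap) { v <- rep(0L, 6); v[hap] <- 1L; v }
  H <- cbind(c(1L, 0L, 0L, 1L, 0L, 1L),  # boundary site, f = 3/6 (not singleton)
             col(3),                      # owned by diploid 2
             col(1),                      # owned by diploid 1
             c(1L, 1L, 0L, 0L, 1L, 0L),  # test SNP: g = (2, 0, 1)
             col(2),                      # owned by diploid 1
             col(5),                      # owned by diploid 3
             c(0L, 1L, 1L, 0L, 1L, 0L))  # boundary site
  panel <- suppressWarnings(phased_panel(H, c(1, 10, 40, 50, 60, 90, 99) * 1e3))
  st <- site_table(panel)
  d <- collect_singleton_distances(panel, st, test_snp = 4L)
  expect_equal(d$genotype, c(2L, 0L, 1L))
  expect_equal(d$left_distance, c(10000, 40000, 49000))
  expect_equal(d$left_censored, c(FALSE, FALSE, TRUE))
  expect_equal(d$right_distance, c(10000, 49000, 40000))
  expect_equal(d$right_censored, c(FALSE, TRUE, FALSE))
  # a singleton cannot be scored as a test SNP
  expect_error(collect_singleton_distances(panel, st, 2L), "singleton")
})

test_that("the raw score is unidentifiable without a genotype contrast", {
  d <- model_distances(50, 1e5, 1e5, 0.5, seed = 1)
  d$genotype <- 1L
  expect_error(raw_sds(d, 0.5), "two genotype classes")
})

test_that("symmetric data yield scores near zero", {
  t_scores <- vapply(1:20, function(s) {
    fit <- raw_sds(model_distances(200, 1e5, 1e5, 0.5, seed = s), 0.5)
    fit$r_hat / fit$se
  }, numeric(1))
  expect_lt(abs(mean(t_scores)), 3 / sqrt(20))
  expect_true(all(abs(t_scores) < 4))
})

test_that("a two-fold tip-length contrast is recovered", {
  r <- vapply(1:8, function(s)
    raw_sds(model_distances(200, 1e5, 2e5, 0.5, seed = s), 0.5)$r_hat,
    numeric(1))
  expect_lt(abs(mean(r) - log(2)), 0.15)
})

test_that("polarization flips negate the raw score", {
  d <- model_distances(150, 1e5, 2e5, 0.4, seed = 3)
  flipped <- d
  flipped$genotype <- 2L - d$genotype
  expect_equal(raw_sds(d, 0.4)$r_hat, -raw_sds(flipped, 0.6)$r_hat,
               tolerance = 1e-6)
})

test_that("heavier censoring preserves the sign of a strong contrast", {
  for (s in 1:5) {
    full <- raw_sds(model_distances(200, 1e5, 2e5, 0.5, seed = s), 0.5)
    cens <- raw_sds(model_distances(200, 1e5, 2e5, 0.5, seed = s,
                                    boundary = 1.5e5), 0.5)
    expect_gt(full$r_hat, 0)
    expect_gt(cens$r_hat, 0)
  }
})

test_that("DAF-binned normalization is a per-bin self-standardization", {
  set.seed(10)
  f <- rep(seq(0.055, 0.945, by = 0.01), each = 10)  # 10 sites per bin
  n <- length(f)
  trk <- data.frame(chrom = "1", position_bp = seq_len(n), site = seq_len(n),
                    derived_freq = f, raw = rnorm(n, sd = 2),
                    standardized = NA_real_, pvalue = NA_real_)
  class(trk) <- c("ScoreTrack", "data.frame")
  out <- normalize_sds(trk)
  z <- out$standardized
  bin <- floor(f * 100)
  expect_lt(max(abs(tapply(z, bin, mean))), 1e-12)
  expect_lt(max(abs(tapply(z, bin, sd) - 1)), 1e-12)
  expect_equal(out$pvalue, 2 * pnorm(-abs(z)))
  # a z of 1.96 corresponds to p ~= 0.05
  expect_equal(2 * pnorm(-1.96), 0.05, tolerance = 0.001)
})

test_that("degenerate zero-variance normalization errors out", {
  trk <- data.frame(chrom = "1", position_bp = 1:10, site = 1:10,
                    derived_freq = rep(0.5, 10), raw = rep(1.3, 10),
                    standardized = NA_real_, pvalue = NA_real_)
  class(trk) <- c("ScoreTrack", "data.frame")
  expect_error(normalize_sds(trk), "zero score variance")
})

test_that("gamma-shape tables are read and applied by DAF bin and genotype", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("f_bin\tgenotype\tshape",
               "0.50\t0\t1.5", "0.50\t1\t2.5", "0.50\t2\t3.5"), f)
  model <- read_gamma_shapes(f)
  k <- admixscan:::kappa_lookup(model, 0.505, c(0L, 1L, 2L))
  expect_equal(k, c(1.5, 2.5, 3.5))
  # bins without an entry fall back to the exponential-tip shape 2
  expect_equal(admixscan:::kappa_lookup(model, 0.3, 0:2), rep(2, 3))
})

test_that("scan-level scores flag undefined sites and stay reproducible", {
  sim <- simulate_panel(sweep_sim_config(n_diploids = 30, seq_len_bp = 5e5,
                                         mu = 5e-7, rho = 1e-7, Ne = 100,
                                         s = 0, seed = 17))
  ts <- select_test_snps(sim$sites, sim$panel)
  trk <- sds_scan(sim$panel, sim$sites, ts)
  expect_equal(nrow(trk), length(ts))
  expect_true(all(is.finite(trk$standardized[!is.na(trk$raw)])))
  trk2 <- sds_scan(sim$panel, sim$sites, ts)
  expect_identical(trk$raw, trk2$raw)
})
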