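test_that("a mutation-free simulation yields a valid empty panel", {
  cfg <- sweep_sim_config(n_diploids = 10, seq_len_bp = 1e5, mu = 0,
                          rho = 1e-8, Ne = 50, s = 0, seed = 1)
  sim <- simulate_panel(cfg)
  expect_s3_class(sim$panel, "PhasedPanel")
  expect_equal(ncol(sim$panel$haplotypes), 0L)
  expect_equal(nrow(sim$sites), 0L)
  expect_true(is.na(sim$selected_site_index))
})

test_that("neutral segregating-site counts match the Watterson expectation", {
  n_hap <- 100
  theta <- 4 * 100 * 1e-8 * 1e6
  a1 <- sum(1 / seq_len(n_hap - 1))
  a2 <- sum(1 / seq_len(n_hap - 1)^2)
  expected <- theta * a1
  sd_one <- sqrt(theta * a1 + theta^2 * a2)
  S <- vapply(1:20, function(i) {
    cfg <- sweep_sim_config(n_diploids = 50, seq_len_bp = 1e6, mu = 1e-8,
                            rho = 1e-8, Ne = 100, s = 0, seed = 1000 + i)
    nrow(simulate_panel(cfg)$sites)
  }, numeric(1))
  expect_lt(abs(mean(S) - expected), 3 * sd_one / sqrt(20))
})

test_that("the neutral unfolded SFS has the expected singleton share", {
  n_hap <- 40
  pred <- 1 / sum(1 / seq_len(n_hap - 1))
  prop <- vapply(1:20, function(i) {
    cfg <- sweep_sim_config(n_diploids = 20, seq_len_bp = 1e6, mu = 5e-8,
                            rho = 1e-8, Ne = 200, s = 0, seed = 2000 + i)
    st <- simulate_panel(cfg)$sites
    mean(st$is_singleton)
  }, numeric(1))
  expect_lt(abs(mean(prop) - pred), 3 * sd(prop) / sqrt(20))
})

test_that("sweep replicates honour the panel frequency condition", {
  cfg <- sweep_sim_config(n_diploids = 20, seq_len_bp = 5e5, mu = 5e-7,
                          rho = 1e-8, Ne = 100, s = 0.05,
                          freq_condition = 0.8, seed = 11)
  sim <- simulate_panel(cfg)
  idx <- sim$selected_site_index
  expect_false(is.na(idx))
  expect_equal(sim$sites$position_bp[idx], cfg$sel_pos_bp)
  expect_gte(sim$sites$derived_freq[idx], 0.8)
  expect_lt(sim$sites$derived_freq[idx], 1)
})

test_that("sweep sites carry excess derived-allele homozygosity", {
  wins <- vapply(1:10, function(i) {
    swp <- simulate_panel(sweep_sim_config(
      n_diploids = 20, seq_len_bp = 5e5, mu = 5e-7, rho = 1e-8, Ne = 100,
      s = 0.05, freq_condition = 0.8, seed = 3000 + i))
    neu <- simulate_panel(sweep_sim_config(
      n_diploids = 20, seq_len_bp = 5e5, mu = 5e-7, rho = 1e-8, Ne = 100,
      s = 0, seed = 3100 + i))
    f_sel <- swp$sites$derived_freq[swp$selected_site_index]
    f_sel^2 > median(neu$sites$derived_freq^2)
  }, logical(1))
  expect_gte(sum(wins), 8)
})

test_that("simulation output is bit-reproducible given config and seed", {
  cfg <- sweep_sim_config(n_diploids = 10, seq_len_bp = 2e5, mu = 5e-7,
                          rho = 1e-7, Ne = 50, s = 0, seed = 99)
  a <- simulate_panel(cfg)
  b <- simulate_panel(cfg)
  expect_identical(a$panel$haplotypes, b$panel$haplotypes)
  expect_identical(a$panel$positions_bp, b$panel$positions_bp)
  c2 <- simulate_panel_pair(cfg)
  d2 <- simulate_panel_pair(cfg)
  expect_identical(c2$panel_a$haplotypes, d2$panel_a$haplotypes)
  expect_identical(c2$panel_b$haplotypes, d2$panel_b$haplotypes)
})

test_that("exhausting the rejection budget fails loudly, naming the budget", {
  cfg <- sweep_sim_config(n_diploids = 10, seq_len_bp = 1e5, mu = 1e-7,
                          rho = 1e-8, Ne = 30, s = 0.01,
                          freq_condition = 0.999, seed = 5,
                          burnin_factor = 8, max_attempts = 2,
                          max_sweep_gens = 4)
  expect_error(simulate_panel(cfg), "budget of 2")
})

test_that("config invariants are enforced", {
  expect_error(sweep_sim_config(n_diploids = 1, seq_len_bp = 1e5))
  expect_error(sweep_sim_config(n_diploids = 10, seq_len_bp = 1e5, s = 1.5))
  expect_error(sweep_sim_config(n_diploids = 10, seq_len_bp = 1e5,
                                sel_pos_bp = 1e5))
  expect_error(sweep_sim_config(n_diploids = 10, seq_len_bp = 1e5,
                                freq_condition = 2))
})

test_that("paired panels share coordinates and keep samples disjoint", {
  cfg <- sweep_sim_config(n_diploids = 15, seq_len_bp = 2e5, mu = 1e-6,
                          rho = 1e-7, Ne = 50, s = 0, seed = 7)
  pair <- simulate_panel_pair(cfg)
  expect_identical(pair$panel_a$positions_bp, pair$panel_b$positions_bp)
  # disjoint draws: the two panels cannot be identical row sets
  expect_false(identical(pair$panel_a$haplotypes, pair$panel_b$haplotypes))
  seg <- colSums(pair$panel_a$haplotypes) + colSums(pair$panel_b$haplotypes)
  expect_true(all(seg >= 1))
})
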