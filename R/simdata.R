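#' Configuration for Wright-Fisher sweep/neutral panel simulation
#'
#' Parameters of the forward Wright-Fisher simulator: a diploid population
#' of size `Ne` evolving on a continuous sequence of `seq_len_bp` bases
#' with per-bp per-generation mutation rate `mu` and recombination rate
#' `rho`. After a neutral burn-in of `burnin_factor * Ne` generations, a
#' derived allele may be injected at `sel_pos_bp` at frequency `1/(2 Ne)`
#' and driven by additive selection with coefficient `s`; replicates are
#' rejection-sampled until the returned panel's derived frequency at that
#' site is at least `freq_condition`.
#'
#' @param n_diploids number of diploid individuals sampled into the panel
#'   (at most `Ne`).
#' @param seq_len_bp sequence length in bp.
#' @param mu per-bp per-generation mutation rate.
#' @param rho per-bp per-generation recombination rate.
#' @param Ne effective (and census) diploid population size.
#' @param s selection coefficient of the derived allele at the selected
#'   site; 0 simulates neutrality.
#' @param sel_pos_bp position of the selected site in `[0, seq_len_bp)`.
#' @param freq_condition minimum present-day derived frequency at the
#'   selected site for a replicate to be accepted.
#' @param seed RNG seed; identical config + seed gives identical output.
#' @param burnin_factor burn-in length in units of `Ne` generations
#'   (at least 8).
#' @param max_attempts rejection-sampling budget for sweep replicates.
#' @param max_sweep_gens cap on post-injection generations per attempt.
#' @return a `SweepSimConfig` list.
#' @export
sweep_sim_config <- function(n_diploids, seq_len_bp, mu = 1e-7, rho = 1e-8,
                             Ne = 500, s = 0, sel_pos_bp = seq_len_bp / 2,
                             freq_condition = 0, seed = 1,
                             burnin_factor = 8, max_attempts = 200,
                             max_sweep_gens = NULL) {
  stopifnot(n_diploids >= 2, s >= 0, s <= 1,
            freq_condition >= 0, freq_condition <= 1,
            sel_pos_bp >= 0, sel_pos_bp < seq_len_bp,
            Ne >= n_diploids, burnin_factor >= 8)
  if (is.null(max_sweep_gens)) max_sweep_gens <- 20L * Ne
  structure(list(n_diploids = as.integer(n_diploids),
                 seq_len_bp = as.numeric(seq_len_bp),
                 mu = mu, rho = rho, Ne = as.integer(Ne), s = s,
                 sel_pos_bp = as.numeric(sel_pos_bp),
                 freq_condition = freq_condition,
                 seed = as.integer(seed),
                 burnin_factor = burnin_factor,
                 max_attempts = as.integer(max_attempts),
                 max_sweep_gens = as.integer(max_sweep_gens)),
            class = "SweepSimConfig")
}

# sample n_diploids individuals (pairs of haplotypes) from a population
sample_panel_haps <- function(pop, n_diploids) {
  Nd <- length(pop) %/% 2L
  ind <- sample.int(Nd, n_diploids)
  idx <- as.vector(rbind(2L * ind - 1L, 2L * ind))
  pop[idx]
}

# build a PhasedPanel + SiteTable from sparse haplotypes (lists of derived
# positions); only sites segregating in the sample are retained, which
# keeps every singleton
panel_from_sparse <- function(haps, config, chrom = "1") {
  pos <- sort(unique(unlist(haps)))
  n_hap <- length(haps)
  if (length(pos) == 0L) {
    H <- matrix(integer(0), nrow = n_hap, ncol = 0)
  } else {
    H <- matrix(0L, nrow = n_hap, ncol = length(pos))
    for (h in seq_len(n_hap))
      H[h, match(haps[[h]], pos)] <- 1L
    seg <- colSums(H)
    keep <- seg >= 1L & seg < n_hap
    H <- H[, keep, drop = FALSE]
    pos <- pos[keep]
  }
  panel <- phased_panel(H, pos, positions_cM = pos * config$rho * 100,
                        chrom = chrom)
  panel
}

#' Simulate a neutral or sweep haplotype panel
#'
#' Forward Wright-Fisher simulation with recombination on a continuous
#' sequence. Sites are polarized against the founding allele (0 =
#' ancestral), every variant segregating in the sample is retained --
#' including singletons -- and the genetic map is uniform at
#' `100 * rho` cM/bp. For `s > 0` the replicate is rejection-sampled from
#' a saved burn-in state until the panel frequency at the selected site
#' reaches `freq_condition`; exhaustion of the attempt budget is an error
#' naming the budget.
#'
#' @param config a [sweep_sim_config()].
#' @return a list with elements `panel` (a [phased_panel()]), `sites`
#'   (a [site_table()]), `selected_site_index` (index into the site table,
#'   or `NA` for neutral runs), `sel_frequency`, `sweep_generations` and
#'   `attempts`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "SweepSimConfig"))
  set.seed(config$seed)
  sim <- simulate_population(config)
  finish_panel(sim, config)
}

# burn in (and, for s > 0, run the rejection-sampled sweep phase);
# returns sparse sample haplotypes. Assumes the RNG seed is already set.
simulate_population <- function(config) {
  Ne <- config$Ne
  pop <- rep(list(numeric(0)), 2L * Ne)
  burn <- wf_evolve_cpp(pop, config$seq_len_bp, config$mu, config$rho,
                        as.integer(round(config$burnin_factor * Ne)),
                        0, -1, -1, 50L)$haps
  if (config$s == 0) {
    return(list(haps = sample_panel_haps(burn, config$n_diploids),
                sel_freq = NA_real_, sweep_gens = 0L, attempts = 0L))
  }
  sweep_from_state(burn, config)
}

finish_panel <- function(sim, config, chrom = "1") {
  panel <- panel_from_sparse(sim$haps, config, chrom = chrom)
  sites <- site_table(panel)
  sel_idx <- NA_integer_
  if (config$s > 0) {
    sel_idx <- match(config$sel_pos_bp, panel$positions_bp)
    if (is.na(sel_idx))
      stop("selected site lost from the sampled panel")  # not reachable
  }
  list(panel = panel, sites = sites, selected_site_index = sel_idx,
       sel_frequency = sim$sel_freq,
       sweep_generations = sim$sweep_gens, attempts = sim$attempts)
}

#' Simulate a target/outgroup population pair
#'
#' Shared neutral burn-in; the outgroup panel ("B") is sampled directly
#' from the burned-in population (a diverse reference, like an outgroup
#' cohort), while the target population ("A") continues forward --
#' optionally through `split_gens` extra neutral generations and then
#' the sweep phase of `config` (rejection-sampled when `s > 0`) -- and
#' is sampled at acceptance. Both panels are expressed on the union of
#' their segregating sites so cross-population statistics see shared
#' coordinates.
#'
#' @param config a [sweep_sim_config()]; `n_diploids` is the per-panel
#'   sample size.
#' @param split_gens extra neutral generations separating the target
#'   from the outgroup before the sweep phase (default 0).
#' @return list with `panel_a`, `sites_a`, `panel_b`, `sites_b`,
#'   `selected_site_index` (site index on the shared coordinate set),
#'   `sel_frequency`, `sweep_generations`, `attempts`.
#' @export
simulate_panel_pair <- function(config, split_gens = 0L) {
  stopifnot(inherits(config, "SweepSimConfig"))
  if (is.null(split_gens)) split_gens <- 0L
  set.seed(config$seed)
  Ne <- config$Ne
  L <- config$seq_len_bp
  pop <- rep(list(numeric(0)), 2L * Ne)
  burn <- wf_evolve_cpp(pop, L, config$mu, config$rho,
                        as.integer(round(config$burnin_factor * Ne)),
                        0, -1, -1, 50L)$haps
  if (config$s == 0 && split_gens == 0) {
    # both panels drawn from the same standing population: keep the two
    # samples disjoint, as two cohorts would be
    if (Ne < 2L * config$n_diploids)
      stop("need Ne >= 2 * n_diploids to draw disjoint panels")
    ind <- sample.int(Ne, 2L * config$n_diploids)
    pick <- function(ii) burn[as.vector(rbind(2L * ii - 1L, 2L * ii))]
    haps_b <- pick(ind[seq_len(config$n_diploids)])
    sim_a <- list(haps = pick(ind[-seq_len(config$n_diploids)]),
                  sel_freq = NA_real_, sweep_gens = 0L, attempts = 0L)
    return(shared_panels(sim_a, haps_b, config))
  }
  haps_b <- sample_panel_haps(burn, config$n_diploids)
  state_a <- if (split_gens > 0)
    wf_evolve_cpp(burn, L, config$mu, config$rho, as.integer(split_gens),
                  0, -1, -1, 50L)$haps
  else burn
  sim_a <- if (config$s == 0) {
    list(haps = sample_panel_haps(state_a, config$n_diploids),
         sel_freq = NA_real_, sweep_gens = 0L, attempts = 0L)
  } else {
    sweep_from_state(state_a, config)
  }
  shared_panels(sim_a, haps_b, config)
}

sweep_from_state <- function(state, config) {
  for (attempt in seq_len(config$max_attempts)) {
    pop <- wf_inject_cpp(state, config$sel_pos_bp)
    gens_left <- config$max_sweep_gens
    total_gens <- 0L
    repeat {
      step <- wf_evolve_cpp(pop, config$seq_len_bp, config$mu, config$rho,
                            min(gens_left, 200L), config$s,
                            config$sel_pos_bp, config$freq_condition, 50L)
      pop <- step$haps
      total_gens <- total_gens + step$gens_run
      gens_left <- gens_left - step$gens_run
      if (step$sel_freq == 0 || gens_left <= 0L) break
      if (step$sel_freq >= config$freq_condition) {
        for (redraw in 1:5) {
          haps <- sample_panel_haps(pop, config$n_diploids)
          f_panel <- mean(vapply(haps, function(h)
            config$sel_pos_bp %in% h, logical(1)))
          if (f_panel >= config$freq_condition && f_panel < 1)
            return(list(haps = haps, sel_freq = f_panel,
                        sweep_gens = total_gens, attempts = attempt))
        }
        break
      }
    }
  }
  stop(sprintf(paste("sweep rejection sampling did not meet the frequency",
                     "condition within the budget of %d replicate attempts"),
               config$max_attempts))
}

shared_panels <- function(sim_a, haps_b, config, chrom = "1") {
  pos <- sort(unique(c(unlist(sim_a$haps), unlist(haps_b))))
  build <- function(haps) {
    H <- matrix(0L, nrow = length(haps), ncol = length(pos))
    for (h in seq_along(haps))
      H[h, match(haps[[h]], pos)] <- 1L
    H
  }
  Ha <- build(sim_a$haps)
  Hb <- build(haps_b)
  seg <- (colSums(Ha) + colSums(Hb))
  keep <- seg >= 1L & seg < (nrow(Ha) + nrow(Hb))
  pos <- pos[keep]
  cm <- pos * config$rho * 100
  panel_a <- phased_panel(Ha[, keep, drop = FALSE], pos, cm, chrom = chrom)
  panel_b <- phased_panel(Hb[, keep, drop = FALSE], pos, cm, chrom = chrom)
  sel_idx <- if (config$s > 0) match(config$sel_pos_bp, pos) else NA_integer_
  list(panel_a = panel_a, sites_a = site_table(panel_a),
       panel_b = panel_b, sites_b = site_table(panel_b),
       selected_site_index = sel_idx,
       sel_frequency = sim_a$sel_freq,
       sweep_generations = sim_a$sweep_gens, attempts = sim_a$attempts)
}
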