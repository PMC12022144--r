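#' Pipeline run configuration
#'
#' Builds the configuration for an end-to-end run: simulate (or read)
#' phased panels for a target and an outgroup population plus a local
#' ancestry mosaic, filter test SNPs, score SDS and XP-EHH, call peaks,
#' scan for local ancestry deviations, and intersect LAD regions with
#' selection peaks. Exactly one of `sim` / `input` must be supplied per
#' data role.
#'
#' @param sim list for simulation-driven runs:
#'   `sweep` (a [sweep_sim_config()]; the target population, with the
#'   outgroup drawn from its ancestral pool), `tracts` (a
#'   [tract_sim_config()]), optional `n_chromosomes` of additional
#'   neutral chromosomes backing the genome-wide standardization
#'   (default 0), optional `split_gens`, optional `lad_baseline_chroms`
#'   baseline-only mosaic chromosomes for the genomic LAD mean/SD
#'   (default 100).
#' @param input list for data-driven runs: `vcf_target`, `vcf_outgroup`
#'   (paths), optional `map` (genetic map path), `ancestry` (msp.tsv
#'   path), `excluded` (BED path), `ancestry_of_interest` (label).
#' @param methods which scans to run (subset of `"sds"`, `"xpehh"`).
#' @param peak_config a [peak_calling_config()].
#' @param lad_preset `"strict"` (4.42 SD) or `"lenient"` (3 SD).
#' @param lad_gap_sites merge tolerance for the LAD scan.
#' @param maf_min,maf_max test-SNP MAF bounds.
#' @param seed run seed; every stochastic stage derives from it.
#' @param out_dir optional output directory; when set, score tracks
#'   (TSV), peaks and LAD regions (BED), the joint candidate table and
#'   a JSON manifest are written.
#' @return a `RunConfig` list.
#' @export
run_config <- function(sim = NULL, input = NULL,
                       methods = c("sds", "xpehh"),
                       peak_config = peak_calling_config(),
                       lad_preset = "strict", lad_gap_sites = 0,
                       maf_min = 0.05, maf_max = 0.95,
                       seed = 1, out_dir = NULL) {
  if (is.null(sim) == is.null(input))
    stop("exactly one of `sim` or `input` must be given")
  methods <- match.arg(methods, c("sds", "xpehh"), several.ok = TRUE)
  structure(list(sim = sim, input = input, methods = methods,
                 peak_config = peak_config, lad_preset = lad_preset,
                 lad_gap_sites = lad_gap_sites,
                 maf_min = maf_min, maf_max = maf_max,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "RunConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' The YAML mirrors the arguments of [run_config()]; `sim$sweep` and
#' `sim$tracts` blocks are passed to [sweep_sim_config()] /
#' [tract_sim_config()], and `peaks` to [peak_calling_config()].
#'
#' @param path YAML file path.
#' @return a `RunConfig`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$sim)) {
    sim <- list(
      sweep = do.call(sweep_sim_config, y$sim$sweep),
      tracts = if (!is.null(y$sim$tracts))
        do.call(tract_sim_config, y$sim$tracts),
      n_chromosomes = y$sim$n_chromosomes %||% 0L,
      split_gens = y$sim$split_gens,
      lad_baseline_chroms = y$sim$lad_baseline_chroms)
  }
  pk <- if (!is.null(y$peaks)) do.call(peak_calling_config, y$peaks)
        else peak_calling_config()
  run_config(sim = sim, input = y$input,
             methods = y$methods %||% c("sds", "xpehh"),
             peak_config = pk,
             lad_preset = y$lad_preset %||% "strict",
             lad_gap_sites = y$lad_gap_sites %||% 0,
             maf_min = y$maf_min %||% 0.05,
             maf_max = y$maf_max %||% 0.95,
             seed = y$seed %||% 1,
             out_dir = y$out_dir)
}

#' Run the full scan pipeline
#'
#' Executes the configured stages in order: data acquisition
#' (simulation or file input), test-SNP filtering, XP-EHH and/or SDS
#' scoring with genome-wide standardization, peak calling, the LAD scan,
#' and the LAD-by-peak intersection that yields post-admixture selection
#' candidates. Deterministic given config + seed. Any stage error is
#' re-raised with the stage name.
#'
#' @param config a [run_config()] or the path to a YAML file for
#'   [read_run_config()].
#' @return list with `tracks` (named list of `ScoreTrack`s), `peaks`
#'   (named list of `PeakSet`s), `lad` (a `LADRegionSet`), `joint`
#'   (post-admixture candidate table), `test_sites`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "RunConfig"))
  set.seed(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  data <- if (!is.null(config$sim)) stage("simulate", pipeline_simulate(config))
          else stage("read-input", pipeline_read_input(config))

  filter_one <- function(chr)
    select_test_snps(chr$sites_a, chr$panel_a, config$maf_min,
                     config$maf_max, excluded = data$excluded)
  test_sites <- stage("filter", lapply(data$chroms, filter_one))

  tracks <- list()
  if ("xpehh" %in% config$methods && !is.null(data$chroms[[1]]$panel_b)) {
    tracks$XPEHH <- stage("xpehh", {
      parts <- Map(function(chr, ts) {
        # score on the pooled-MAF panel (the variants common in the
        # merged sample), at the target population's test SNPs
        keep <- pooled_maf_sites(chr$panel_a, chr$panel_b, config$maf_min)
        pa <- subset_panel(chr$panel_a, chr$panel_a$positions_bp[keep])
        pb <- subset_panel(chr$panel_b, chr$panel_b$positions_bp[keep])
        ts_keep <- intersect(ts, keep)
        cores <- match(ts_keep, keep)
        tr <- xpehh(pa, pb, cores, standardize = FALSE)
        tr$site <- ts_keep  # site indices on the full coordinate set
        tr
      }, data$chroms, test_sites)
      tr <- do.call(rbind, parts)
      attr(tr, "method") <- "XPEHH"
      class(tr) <- c("ScoreTrack", "data.frame")
      standardize_track(tr)
    })
  }
  if ("sds" %in% config$methods) {
    tracks$SDS <- stage("sds", {
      chroms_sds <- Map(function(chr, ts)
        list(panel = chr$panel_a, sites = chr$sites_a, test_sites = ts),
        data$chroms, test_sites)
      sds_scan_genome(chroms_sds)
    })
  }
  peaks <- stage("peaks",
                 lapply(tracks, call_peaks, config = config$peak_config))

  lad <- NULL
  joint <- NULL
  if (!is.null(data$ancestry_track)) {
    lad <- stage("lad", lad_scan(
      data$ancestry_track,
      threshold_sd = lad_threshold(config$lad_preset),
      baseline = data$ancestry_baseline,
      gap_sites = config$lad_gap_sites,
      ancestry_label = data$ancestry_label))
    joint <- stage("overlap", {
      parts <- lapply(peaks, function(p) lad_peak_overlap(lad, p))
      do.call(rbind, parts[vapply(parts, nrow, 0L) >= 0])
    })
    if (is.null(joint)) joint <- lad_peak_overlap(lad[0, ], NULL)
  }

  manifest <- list(
    package = "admixscan",
    version = as.character(packageVersion("admixscan")),
    seed = config$seed,
    methods = config$methods,
    lad_preset = config$lad_preset,
    n_chromosomes = length(data$chroms),
    n_test_snps = sum(lengths(test_sites)),
    n_peaks = vapply(peaks, nrow, 0L),
    n_lad_regions = if (is.null(lad)) NA_integer_ else nrow(lad),
    n_joint_candidates = if (is.null(joint)) NA_integer_ else nrow(joint),
    selected_site = data$selected %||% NULL,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  result <- list(tracks = tracks, peaks = peaks, lad = lad, joint = joint,
                 test_sites = test_sites, data = data, manifest = manifest)
  if (!is.null(config$out_dir))
    stage("write-output", write_pipeline_outputs(result, config))
  result
}

pipeline_simulate <- function(config) {
  sim <- config$sim
  sweep_cfg <- sim$sweep
  n_extra <- sim$n_chromosomes %||% 0L
  chroms <- list()
  seeds <- config$seed + seq_len(n_extra + 1L) * 1000L
  pair <- simulate_panel_pair(modify_config(sweep_cfg, seed = seeds[1]),
                              split_gens = sim$split_gens)
  pair$panel_a$chrom <- "1"; pair$panel_b$chrom <- "1"
  pair$sites_a$chrom <- "1"; pair$sites_b$chrom <- "1"
  chroms[["1"]] <- pair
  if (n_extra > 0) {
    for (k in seq_len(n_extra)) {
      cfg_k <- modify_config(sweep_cfg, s = 0, freq_condition = 0,
                             seed = seeds[k + 1L])
      pk <- simulate_panel_pair(cfg_k, split_gens = sim$split_gens)
      lab <- as.character(k + 1L)
      pk$panel_a$chrom <- lab; pk$panel_b$chrom <- lab
      pk$sites_a$chrom <- lab; pk$sites_b$chrom <- lab
      chroms[[lab]] <- pk
    }
  }
  selected <- if (!is.na(pair$selected_site_index))
    list(chrom = "1",
         position_bp = pair$panel_a$positions_bp[pair$selected_site_index],
         frequency = pair$sel_frequency)
  ancestry_track <- NULL
  ancestry_baseline <- NULL
  ancestry_label <- NA_character_
  if (!is.null(sim$tracts)) {
    tcfg <- modify_config(sim$tracts, seed = config$seed + 77L)
    lab_k <- tcfg$ancestry_labels[tcfg$sel_ancestry]
    # emit ancestry on each chromosome's site grid (cM from the panel map)
    tracks <- list()
    for (lab in names(chroms)) {
      grid <- chroms[[lab]]$panel_a$positions_cM
      grid <- pmin(grid, tcfg$chrom_len_cM)
      # the selected-locus boost only applies on the sweep chromosome
      tc <- tcfg
      if (lab != "1") tc$sel_locus_cM <- NULL
      tc$seed <- tcfg$seed + as.integer(lab)
      ts <- simulate_tracts(tc, grid_cM = grid)
      am <- ts$ancestry
      am$positions_bp <- chroms[[lab]]$panel_a$positions_bp
      am$chrom <- lab
      tr <- ancestry_proportion(am, lab_k)
      tracks[[lab]] <- tr
    }
    ancestry_track <- do.call(rbind, tracks)
    # genomic baseline: extra neutral-mosaic chromosomes so the
    # "mean genomic LAD" reflects the genome, not just the scanned region
    n_base <- sim$lad_baseline_chroms %||% 100L
    base_tracks <- vector("list", n_base)
    for (k in seq_len(n_base)) {
      tb <- tcfg
      tb$sel_locus_cM <- NULL
      tb$seed <- tcfg$seed + 500L + k
      tsb <- simulate_tracts(tb, grid_cM = seq(0, tcfg$chrom_len_cM,
                                               length.out = 200L))
      amb <- tsb$ancestry
      amb$chrom <- sprintf("base%d", k)
      base_tracks[[k]] <- ancestry_proportion(amb, lab_k)
    }
    ancestry_baseline <- rbind(ancestry_track,
                               do.call(rbind, base_tracks))
    ancestry_label <- lab_k
  }
  list(chroms = chroms, ancestry_track = ancestry_track,
       ancestry_baseline = ancestry_baseline,
       ancestry_label = ancestry_label, excluded = NULL,
       selected = selected)
}

modify_config <- function(cfg, ...) {
  new <- utils::modifyList(unclass(cfg), list(...))
  class(new) <- class(cfg)
  new
}

pipeline_read_input <- function(config) {
  input <- config$input
  map <- if (!is.null(input$map)) read_genetic_map(input$map)
  tgt <- read_phased_vcf(input$vcf_target,
                         ancestral_source = input$ancestral_source %||% "AA",
                         map = map)
  chr <- list(panel_a = tgt$panel, sites_a = tgt$sites,
              panel_b = NULL, sites_b = NULL)
  if (!is.null(input$vcf_outgroup)) {
    outg <- read_phased_vcf(input$vcf_outgroup,
                            ancestral_source = input$ancestral_source %||% "AA",
                            map = map)
    shared <- intersect(tgt$panel$positions_bp, outg$panel$positions_bp)
    chr$panel_a <- subset_panel(tgt$panel, shared)
    chr$sites_a <- site_table(chr$panel_a)
    chr$panel_b <- subset_panel(outg$panel, shared)
    chr$sites_b <- site_table(chr$panel_b)
  }
  excluded <- if (!is.null(input$excluded)) read_bed(input$excluded)
  ancestry_track <- NULL
  ancestry_label <- NA_character_
  if (!is.null(input$ancestry)) {
    am <- read_ancestry_table(input$ancestry,
                              positions_bp = chr$panel_a$positions_bp,
                              sample_ids = chr$panel_a$sample_ids)
    ancestry_label <- input$ancestry_of_interest %||% am$labels[1]
    ancestry_track <- ancestry_proportion(am, ancestry_label)
    ancestry_track$chrom <- chr$panel_a$chrom
  }
  chroms <- list(chr)
  names(chroms) <- chr$panel_a$chrom
  list(chroms = chroms, ancestry_track = ancestry_track,
       ancestry_label = ancestry_label, excluded = excluded,
       selected = NULL)
}

#' Restrict a panel to a subset of physical positions
#'
#' @param panel a [phased_panel()].
#' @param positions_bp positions to keep (must exist in the panel).
#' @return the subset [phased_panel()].
#' @export
subset_panel <- function(panel, positions_bp) {
  keep <- match(sort(positions_bp), panel$positions_bp)
  if (anyNA(keep)) stop("positions not present in panel")
  phased_panel(panel$haplotypes[, keep, drop = FALSE],
               panel$positions_bp[keep],
               positions_cM = panel$positions_cM[keep],
               chrom = panel$chrom, sample_ids = panel$sample_ids)
}

write_pipeline_outputs <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(config$out_dir, ...)
  for (nm in names(result$tracks))
    write_score_track(result$tracks[[nm]],
                      p(sprintf("track_%s.tsv", tolower(nm))))
  for (nm in names(result$peaks)) {
    pk <- result$peaks[[nm]]
    if (nrow(pk) > 0) pk$name <- sprintf("%s_peak%d", nm, seq_len(nrow(pk)))
    write_bed(pk, p(sprintf("peaks_%s.bed", tolower(nm))))
  }
  if (!is.null(result$lad)) {
    lad <- result$lad
    if (nrow(lad) > 0)
      lad$name <- sprintf("%s_%s", lad$ancestry, lad$direction)
    write_bed(lad, p("lad_regions.bed"))
  }
  if (!is.null(result$joint))
    utils::write.table(result$joint, p("joint_candidates.tsv"),
                       quote = FALSE, sep = "\t", row.names = FALSE)
  jsonlite::write_json(result$manifest, p("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(config$out_dir)
}
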