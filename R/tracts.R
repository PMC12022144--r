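#' Configuration for admixture-tract simulation
#'
#' Each haplotype is a continuous-position Markov mosaic of `K` ancestries
#' along a chromosome of `chrom_len_cM` centimorgans: ancestry switches
#' occur as a Poisson process with rate `g` per Morgan (the pulse was `g`
#' generations ago, so tract lengths are exponential with mean `100/g`
#' cM), and at each switch the new ancestry is drawn from the stationary
#' proportions `m`. Optionally, the probability of ancestry `sel_ancestry`
#' is raised by `delta` at a selected locus, decaying linearly to zero at
#' `sel_halfwidth_cM` from the locus -- emulating post-admixture selection.
#'
#' @param n_haplotypes number of haplotypes.
#' @param chrom_len_cM genetic length of the chromosome.
#' @param m stationary ancestry proportions (length `K`, summing to 1).
#' @param g generations since the admixture pulse (>= 1).
#' @param sel_locus_cM optional selected-locus position.
#' @param sel_ancestry 1-based index of the favoured ancestry.
#' @param delta local increase of the favoured-ancestry probability at the
#'   locus; must satisfy `0 <= delta <= 1 - m[sel_ancestry]`.
#' @param sel_halfwidth_cM half-width of the linear decay of `delta`.
#' @param seed RNG seed.
#' @param ancestry_labels optional character labels, length `K`.
#' @return a `TractSimConfig` list.
#' @export
tract_sim_config <- function(n_haplotypes, chrom_len_cM, m, g,
                             sel_locus_cM = NULL, sel_ancestry = 1L,
                             delta = 0, sel_halfwidth_cM = 5,
                             seed = 1, ancestry_labels = NULL) {
  m <- as.numeric(m)
  if (abs(sum(m) - 1) > 1e-12)
    stop("ancestry proportions m must sum to 1")
  if (any(m < 0)) stop("ancestry proportions must be non-negative")
  if (g < 1) stop("g must be at least 1 generation")
  if (!is.null(sel_locus_cM)) {
    if (sel_locus_cM < 0 || sel_locus_cM > chrom_len_cM)
      stop("selected locus outside the chromosome")
    if (delta < 0 || delta > 1 - m[sel_ancestry])
      stop("delta must lie in [0, 1 - m[sel_ancestry]]")
  }
  if (is.null(ancestry_labels))
    ancestry_labels <- sprintf("ANC%d", seq_along(m))
  structure(list(n_haplotypes = as.integer(n_haplotypes),
                 chrom_len_cM = as.numeric(chrom_len_cM),
                 K = length(m), m = m, g = as.numeric(g),
                 sel_locus_cM = sel_locus_cM,
                 sel_ancestry = as.integer(sel_ancestry),
                 delta = delta,
                 sel_halfwidth_cM = as.numeric(sel_halfwidth_cM),
                 seed = as.integer(seed),
                 ancestry_labels = ancestry_labels),
            class = "TractSimConfig")
}

#' Local ancestry matrix
#'
#' Per-haplotype, per-site integer ancestry codes (`0 .. K-1`) on a grid
#' of site positions.
#'
#' @param codes integer matrix, haplotypes x sites, values in `0..K-1`.
#' @param positions_bp site positions (bp).
#' @param labels ancestry labels (length `K`); label `i` is code `i - 1`.
#' @param chrom chromosome label.
#' @return an `AncestryMatrix` object.
#' @export
ancestry_matrix <- function(codes, positions_bp, labels, chrom = "1") {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  K <- length(labels)
  if (ncol(codes) != length(positions_bp))
    stop("positions do not match site count")
  if (nrow(codes) > 0 && ncol(codes) > 0 &&
      (min(codes) < 0L || max(codes) >= K))
    stop("ancestry codes must lie in 0..K-1")
  structure(list(codes = codes, positions_bp = as.numeric(positions_bp),
                 labels = as.character(labels), chrom = as.character(chrom)),
            class = "AncestryMatrix")
}

#' @export
print.AncestryMatrix <- function(x, ...) {
  cat(sprintf("AncestryMatrix: %d haplotypes x %d sites, ancestries: %s\n",
              nrow(x$codes), ncol(x$codes),
              paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' Simulate admixture ancestry mosaics
#'
#' Draws each haplotype as a Markov mosaic (see [tract_sim_config()]) and
#' emits ancestry codes at a user-supplied grid of site positions. When a
#' selected locus is configured, one uniform deviate per haplotype decides
#' whether its assignment within the boosted window is overridden to the
#' favoured ancestry, so that the per-site probability of that ancestry is
#' `m[sel] + delta * max(0, 1 - |x - locus| / halfwidth)` while the
#' override remains contiguous along the haplotype.
#'
#' @param config a [tract_sim_config()].
#' @param grid_cM genetic positions at which to emit assignments
#'   (default: 2,000 evenly spaced sites).
#' @param cM_per_Mb used to derive physical grid positions (default 1).
#' @return a list with `ancestry` (an [ancestry_matrix()]; codes are
#'   0-based), `grid_cM`, and `tract_lengths` (lengths in cM of all
#'   complete inter-switch segments, pooled over haplotypes).
#' @export
simulate_tracts <- function(config, grid_cM = NULL, cM_per_Mb = 1) {
  stopifnot(inherits(config, "TractSimConfig"))
  set.seed(config$seed)
  L <- config$chrom_len_cM
  if (is.null(grid_cM))
    grid_cM <- seq(0, L, length.out = 2000L)
  if (any(grid_cM < 0 | grid_cM > L))
    stop("grid positions outside the chromosome")
  n <- config$n_haplotypes
  K <- config$K
  codes <- matrix(0L, nrow = n, ncol = length(grid_cM))
  tract_lengths <- vector("list", n)
  sel <- !is.null(config$sel_locus_cM) && config$delta > 0
  if (sel) {
    dist <- abs(grid_cM - config$sel_locus_cM)
    delta_x <- config$delta * pmax(0, 1 - dist / config$sel_halfwidth_cM)
    q_x <- delta_x / (1 - config$m[config$sel_ancestry])
  }
  for (h in seq_len(n)) {
    n_switch <- rpois(1L, config$g * L / 100)
    switches <- sort(runif(n_switch, 0, L))
    anc <- sample.int(K, n_switch + 1L, replace = TRUE,
                      prob = config$m) - 1L
    seg <- findInterval(grid_cM, switches)
    codes[h, ] <- anc[seg + 1L]
    if (n_switch >= 2L)
      tract_lengths[[h]] <- diff(switches)
    if (sel) {
      u <- runif(1)
      override <- u < q_x & codes[h, ] != (config$sel_ancestry - 1L)
      codes[h, override] <- config$sel_ancestry - 1L
    }
  }
  pos_bp <- grid_cM * 1e6 / cM_per_Mb
  # emission grids may repeat a physical position only if cM coincide; keep 1:1
  list(ancestry = ancestry_matrix(codes, pos_bp, config$ancestry_labels),
       grid_cM = grid_cM,
       tract_lengths = unlist(tract_lengths))
}
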