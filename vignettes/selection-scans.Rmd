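---
title: "Selection scans and local ancestry deviations with admixscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection scans and local ancestry deviations with admixscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixscan)
```

## What the package computes

`admixscan` implements two haplotype-based genome scans for recent
positive selection and a local-ancestry-deviation scan for
post-admixture selection, together with the simulators needed to
exercise them end to end on synthetic cohorts.

**XP-EHH.** Extended haplotype homozygosity from a core SNP is the
probability that two haplotypes drawn without replacement are identical
over every scored site from the core out to distance $x$:
$EHH(x) = \sum_h \binom{n_h}{2} / \binom{n}{2}$ over the multiplicities
$n_h$ of the distinct extended haplotypes. It is computed over the whole
population (the core allele is part of the extended haplotype), starts
at 1, and is non-increasing. iHH is the trapezoidal integral of the
curve over genetic distance, left plus right of the core, truncated
where EHH first drops below 0.05 (a partial trapezoid runs to the
linearly interpolated crossing). The cross-population statistic at a
site is $\ln(iHH_A / iHH_B)$, standardized to mean 0 and SD 1 over all
defined sites genome-wide in a single bin; large positive values mean
unusually long shared haplotypes in the target population A relative to
the reference B — the footprint of a sweep that has reached high
frequency in A.

**Singleton density score.** A derived allele that has risen recently
sits on haplotypes whose terminal genealogical branches ("tips") are
short, so its carriers own few singletons nearby. For each diploid and
each side of a test SNP the scan records the distance to the nearest
singleton *owned by that individual* (censored at the analysis boundary
when none exists). Modelling singletons as Poisson processes along each
tip, a side-distance for an individual with alleles $a_1, a_2$ is
exponential with rate $1/m_{a_1} + 1/m_{a_2}$, where $m_A$ and $m_D$
are distance scales inversely proportional to the mean ancestral- and
derived-lineage tip lengths; the two sides sum to a Gamma total whose
shape (2 under the exponential model) may be replaced per frequency bin
and genotype by a gamma-shapes table supplied as a configuration
artifact. Because the two-parameter likelihood is weakly identified at
extreme frequencies, the frequency-weighted mean scale
$f\,m_D + (1-f)\,m_A$ is anchored to its neutral expectation estimated
from the genome-wide mean singleton distance in the site's DAF bin
(a censoring-aware exposure/events estimate), and a one-dimensional
profile likelihood is maximized over $r = \log(m_D/m_A) =
\log(\mu_A/\mu_D)$. Positive $r$ means derived tips are shorter — the
derived allele has been rising. Raw scores are standardized in
derived-allele-frequency bins of width 0.01 spanning 0.05–0.95 (bins
with too few sites merge rightwards; degenerate zero-variance bins keep
merging, and a single degenerate bin is an error), and two-sided normal
p-values are attached.

**Peak calling.** A SNP is a candidate when its standardized score
reaches the empirical 99.99% quantile of the genome-wide track, and is
confirmed when the 1 Mb window centred on it holds at least 10
*additional* variants at or above the 99.995% quantile; confirmed
windows are merged and each merged peak reports its maximum-scoring SNP
as the summit. The support quantile is deliberately higher than the
primary one — the rule is implemented exactly as stated. Both
quantiles, the window, the support count, and whether the candidate may
count itself are configurable. A structural consequence worth knowing:
with empirical quantiles, no peak can exist unless the track holds at
least $\mathrm{min\_support}/(1 - \mathrm{support\_quantile})$ scored
sites (200,000 at the defaults), so desk-scale analyses must scale the
quantiles to their track size, as the examples below do.

**Local ancestry deviations.** Given per-haplotype, per-site ancestry
assignments (e.g. expanded from an RFmix `.msp.tsv` table), the
proportion track of an ancestry is compared against its genomic mean
and SD across all sites of all supplied chromosomes. Maximal runs of
sites beyond `mean ± t·SD` are reported with direction (excess or
deficit) and peak z; the named presets are `strict` (4.42 SD) and
`lenient` (3 SD). The scan is two-sided by design — excess is the
reported criterion in post-admixture studies, but a deficit is the
mirror-image signal, so both are returned with a direction label.
Intersecting LAD regions with selection peaks yields the
post-admixture selection candidates.

## The simulators

`simulate_panel()` is a forward Wright–Fisher simulator on a continuous
sequence: per-generation recombination counts are Poisson($\rho L$)
with uniform breakpoints, mutations are Poisson($\mu L$) under
infinite sites, and selection acts additively (fitness $1$, $1+s/2$,
$1+s$). Populations burn in for $8 N_e$ generations from a monomorphic
founder; sites are polarized against the founding allele, and every
variant segregating in the sample — including singletons — is
retained. Sweeps inject a single derived copy into the burned-in
population and are rejection-sampled until the *returned panel's*
frequency at the selected site reaches the configured threshold; an
exhausted attempt budget is an explicit error. `simulate_panel_pair()`
draws the outgroup panel from the burned-in ancestral pool (a diverse
reference population) while the target continues through the sweep;
for fully neutral pairs the two panels are disjoint draws from the
standing population. The genetic map is uniform at $100\rho$ cM/bp
unless a map is supplied — the statistics need genetic distance, not
map realism.

`simulate_tracts()` draws each haplotype as a continuous Markov mosaic:
ancestry switches arrive as a Poisson process with rate $g$ per Morgan
($g$ generations since the admixture pulse, hence exponential tract
lengths with mean $100/g$ cM), and each switch draws the new ancestry
from the stationary proportions $m$. An optional selected locus raises
the favoured ancestry's probability by $\delta$, decaying linearly to
zero at a configurable half-width; one uniform deviate per haplotype
drives the override so that boosted assignments stay contiguous along
the chromosome while the per-site probability is exactly
$m_k + \delta(x)$.

### Default parameter choices

The defaults emulate a desk-scale version of a cohort scan and were
fixed once when the study conditions were designed:

* $\rho = 10^{-8}$ per bp per generation (1 cM/Mb, the canonical
  human-scale rate). Higher rates fragment swept haplotypes so quickly
  at small $N_e$ that cross-population homozygosity carries no signal.
* $\mu = 2\times10^{-7}$ per bp per generation for scan-scale panels —
  a deliberate $\theta$-rescaling so that a 2 Mb replicate carries a
  few thousand SNPs and each haplotype owns a handful of singletons,
  standing in for chromosome-scale data.
* sweep replicates: $N_e = 500$, $s = 0.05$, panels of 100 diploids,
  conditioned on a present-day derived frequency of at least 0.8 at
  the selected site (the regime an ongoing-sweep scan targets).
* tract mosaics: pulse ages of 10–30 generations and minor-ancestry
  proportions around 0.1, the post-admixture regime the LAD scan is
  meant for.

### What the generator does and does not emulate

The simulator reproduces the statistical structure the scans assume:
phased polarized panels with singletons retained, linkage decaying on
the right genetic scale, hard sweeps with frequency conditioning, and
chromosome-scale ancestry mosaics with a stationary genomic background.
It deliberately omits demographic realism — growth, bottlenecks,
migration, variable recombination maps, genotyping error (all Non-goals
of the generator). Two consequences matter for interpreting green
tests. First, real human cohorts carry the imprint of recent explosive
growth, which lengthens terminal branches and is precisely what gives
the singleton density score its power at biobank scale; in a
constant-size desk-scale population the derived/ancestral tip-length
contrast after a conditioned sweep is real but small (we measure
ancestral/derived singleton-load ratios of roughly 1–4 across
replicates), and the per-site score at the selected site only rarely
clears the neutral 99th percentile. The package therefore demonstrates
SDS *calibration* (uniform p-values under neutrality, exact bin
standardization, parameter recovery under its own generative model)
rather than sweep *power* at these population sizes. XP-EHH, which
integrates information across the whole swept haplotype, retains
substantially better desk-scale power, though it too is limited by
genealogical luck: sweeps that complete slowly leave fragmented
haplotypes, and in repeated conditioned replicates the statistic at
the exact selected site clears the neutral genome-wide 99th percentile
in roughly 70–90% of runs, while region-level peak detection (the way
candidate regions are actually called) is more robust. Second, passing tests say nothing about robustness
to phasing error, ancestral misassignment beyond the drop-and-log
policy, or local-ancestry inference error, since those processes are
consumed, not modelled.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; VCF (1-based) and BED
  (0-based half-open) are converted at the boundary. The simulator's
  continuous positions are kept as-is in panels and rounded (with
  collision bumping) only when writing VCF.
* MAF is `min(f, 1-f)` of the polarized derived frequency; test SNPs
  additionally need all three diploid genotype classes and must lie
  outside excluded intervals. Singletons are never test SNPs but stay
  available to the singleton scorer.
* Quantiles are type-7 empirical quantiles over the genome-wide track.
* The SDS profile likelihood is maximized on $r \in [-12, 12]$;
  boundary solutions and non-positive curvature are reported as
  undefined sites rather than numbers. Censored sides contribute
  survival terms with per-side shape $\kappa/2$.
* Cross-population scoring uses the pooled-MAF site set
  (`pooled_maf_sites()`): scoring a panel only at the other
  population's private variants makes it spuriously homozygous.
  `xpehh_pair_scan()` additionally requires test SNPs to be common in
  both populations, mirroring jointly MAF-filtered merged cohorts.
* Degenerate inputs have defined behaviour: an empty track yields an
  empty peak set; a constant ancestry track yields no LAD regions with
  a warning; identical panels make XP-EHH standardization error out
  (zero variance); iHH = 0 is a valid value.

## Desk-scale analysis sizes used by the test-suite

The packaged checks run, and state their conclusions at, the following
problem sizes, chosen as a realistic desk-scale emulation: sweep
replicates of 2 Mb at $N_e = 500$ against 3 neutral backdrop pairs;
a 50,000-site pooled neutral genome for the XP-EHH standardization
contract; 22 chromosomes of 1 Mb with test SNPs thinned to 10 kb
spacing (about 2,000 scanned sites) for SDS calibration — many short
chromosomes are used because the Kolmogorov–Smirnov statistic is
otherwise dominated by per-chromosome genealogical clustering rather
than by miscalibration; and end-to-end runs of a 1 Mb sweep chromosome
plus 3 neutral chromosomes at $N_e = 300$, with a 200-haplotype
ancestry cohort, a local boost of $\delta = 0.15$ and the strict
(4.42 SD) LAD preset. For the same reason given above, the LAD scan's
genomic baseline in the pipeline pools the scanned chromosomes with 100
simulated baseline-only mosaic chromosomes: on a 3-chromosome "genome"
a planted boost would otherwise contaminate its own baseline, whereas
at genome scale the contamination is negligible.

## A worked example

```{r example, eval = FALSE}
library(admixscan)

swp <- sweep_sim_config(n_diploids = 100, seq_len_bp = 1e6, mu = 2e-7,
                        rho = 1e-8, Ne = 300, s = 0.05,
                        freq_condition = 0.8, seed = 7601)
trc <- tract_sim_config(n_haplotypes = 200, chrom_len_cM = 1.001,
                        m = c(0.9, 0.1), g = 30, sel_locus_cM = 0.5,
                        sel_ancestry = 2, delta = 0.15,
                        sel_halfwidth_cM = 0.4, seed = 7601)
cfg <- run_config(sim = list(sweep = swp, tracts = trc, n_chromosomes = 3),
                  methods = "xpehh",
                  peak_config = peak_calling_config(
                    primary_quantile = 0.99, support_quantile = 0.995,
                    window_bp = 1e6, min_support = 5),
                  lad_preset = "strict", seed = 7601,
                  out_dir = "admixscan-demo")
res <- run_pipeline(cfg)
res$peaks$XPEHH   # selection peaks with summits
res$lad           # deviated-ancestry regions
res$joint         # post-admixture selection candidates
```

## Known limitations

Beyond the demographic simplifications above: the per-site SDS model
treats the two sides of a test SNP as independent given the genotype,
which understates the true spread of raw scores on linked data (the
DAF-bin standardization absorbs this on average but the score
distribution keeps slightly non-normal tails); censoring conventions at
chromosome ends are a declared choice (each censored side carries the
boundary distance as a survival term); and the peak rule's empirical
quantiles make its false-positive behaviour depend on track length and
local score correlation, which is why the planted-signal checks use
generous spatial separation.
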