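#' Simulation configuration for a two-kit, three-center cohort
#'
#' Builds and validates the configuration driving the synthetic-cohort
#' generator. Defaults describe a desk-scale analogue of a multi-center
#' exome study: three sequencing centers mapped onto two capture kits
#' (C1 -> KitA, C2/C3 -> KitB), mild European-like substructure, a balanced
#' case/control phenotype with a handful of true risk variants, and
#' variant-specific allelic capture bias in one kit.
#'
#' The capture-bias model has one parameter per variant and kit: the capture
#' efficiency `c`, the relative probability that a template carrying the
#' alternative allele is captured versus a reference template. `c = 1` is
#' unbiased; `c < 1` depresses the heterozygote alternative allele fraction
#' to `c / (1 + c)` and, when small, causes allele dropout. The default
#' biased efficiency 0.02 places the biased heterozygote AAF near
#' `log2(0.02 / 1.02) ~ -5.7`, i.e. a second AAF mode well below the
#' balanced mode at -1.
#'
#' @param n_per_center integer vector of samples per center, named
#'   `C1`, `C2`, `C3`.
#' @param n_variants number of biallelic SNP sites to simulate.
#' @param k_subpops number of subpopulations (Balding-Nichols model).
#' @param fst fixation index F_ST in \[0, 1) controlling subpopulation
#'   allele-frequency divergence; 0 collapses all subpopulations onto the
#'   ancestral frequency.
#' @param ancestral_maf_range length-2 range the ancestral minor allele
#'   frequencies are drawn from (uniform).
#' @param prevalence target expected case fraction; the phenotype-model
#'   intercept is solved numerically to hit it.
#' @param n_causal number of causal variants.
#' @param causal_or odds ratio(s) per alternative allele for causal
#'   variants (recycled to `n_causal`).
#' @param causal_maf ancestral MAF assigned to causal variants (gives them a
#'   common, powered frequency); `NULL` leaves their frequencies random.
#' @param n_biased number of variants with kit-specific capture bias.
#'   Biased variants are chosen among the causal variants first (the
#'   batch-confounded-signal scenario), then among non-causal variants.
#' @param c_biased capture efficiency of the biased kit at biased variants,
#'   in (0, 1\].
#' @param biased_kit which kit carries the bias (default `"KitB"`).
#' @param mean_depth per-kit mean sequencing depth, named `KitA`, `KitB`.
#' @param depth_dispersion negative-binomial size parameter of per-call
#'   depth (smaller = more overdispersed).
#' @param base_error per-read base error rate epsilon.
#' @param min_call_depth genotype calls at depth below this floor are set
#'   missing.
#' @param transition_prob probability a simulated site is a transition
#'   (drives the cohort Ti/Tv ratio; 0.76 gives ~3.2, typical of exomes).
#' @param vqslod_fail_frac fraction of sites given a negative
#'   VQSLOD-style score (site-level QC failures); 0 by default.
#' @param subpop_effects per-subpopulation additive log-odds offsets on the
#'   phenotype (length `k_subpops` or scalar 0). Non-zero values confound
#'   phenotype with substructure.
#' @param seed master integer seed; all stage streams derive from it.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_per_center = c(C1 = 1475L, C2 = 1085L, C3 = 740L),
                       n_variants = 2000L,
                       k_subpops = 3L,
                       fst = 0.01,
                       ancestral_maf_range = c(0.05, 0.5),
                       prevalence = 0.5,
                       n_causal = 10L,
                       causal_or = 3.5,
                       causal_maf = 0.08,
                       n_biased = 8L,
                       c_biased = 0.02,
                       biased_kit = "KitB",
                       mean_depth = c(KitA = 60, KitB = 60),
                       depth_dispersion = 8,
                       base_error = 0.005,
                       min_call_depth = 6L,
                       transition_prob = 0.76,
                       vqslod_fail_frac = 0,
                       subpop_effects = 0,
                       seed = 1L) {
  n_per_center <- as.integer(n_per_center)
  if (length(n_per_center) != 3L) {
    names(n_per_center) <- NULL
  }
  if (is.null(names(n_per_center)) || !all(names(n_per_center) == CENTER_LEVELS)) {
    if (length(n_per_center) != 3L) {
      stop("n_per_center must have one count per center C1, C2, C3")
    }
    names(n_per_center) <- CENTER_LEVELS
  }
  if (any(n_per_center < 1L)) stop("every center must contribute >= 1 sample")
  if (n_variants < 1L) stop("n_variants must be >= 1")
  if (k_subpops < 1L) stop("k_subpops must be >= 1")
  if (fst < 0 || fst >= 1) stop("fst must lie in [0, 1)")
  stopifnot(length(ancestral_maf_range) == 2L)
  if (ancestral_maf_range[1] <= 0 || ancestral_maf_range[2] > 0.5 ||
      diff(ancestral_maf_range) < 0) {
    stop("ancestral_maf_range must be an increasing range within (0, 0.5]")
  }
  if (prevalence <= 0 || prevalence >= 1) {
    stop("prevalence must lie strictly between 0 and 1")
  }
  n_causal <- as.integer(n_causal)
  n_biased <- as.integer(n_biased)
  if (n_causal < 0 || n_causal > n_variants) stop("invalid n_causal")
  if (n_biased < 0 || n_biased > n_variants) stop("invalid n_biased")
  causal_or <- rep_len(as.numeric(causal_or), max(n_causal, 1L))[seq_len(n_causal)]
  if (n_causal > 0 && any(causal_or <= 0)) stop("odds ratios must be > 0")
  if (!is.null(causal_maf) &&
      (causal_maf <= 0 || causal_maf > 0.5)) {
    stop("causal_maf must lie in (0, 0.5]")
  }
  if (c_biased <= 0 || c_biased > 1) stop("c_biased must lie in (0, 1]")
  if (!biased_kit %in% KIT_LEVELS) stop("biased_kit must be KitA or KitB")
  if (is.null(names(mean_depth))) names(mean_depth) <- KIT_LEVELS
  if (!all(KIT_LEVELS %in% names(mean_depth))) {
    stop("mean_depth must be named KitA, KitB")
  }
  if (any(mean_depth <= 0)) stop("mean depths must be positive")
  if (depth_dispersion <= 0) stop("depth_dispersion must be positive")
  if (base_error < 0 || base_error >= 0.5) stop("base_error must lie in [0, 0.5)")
  if (min_call_depth < 1L) stop("min_call_depth must be >= 1")
  if (transition_prob <= 0 || transition_prob >= 1) {
    stop("transition_prob must lie in (0, 1)")
  }
  if (vqslod_fail_frac < 0 || vqslod_fail_frac >= 1) {
    stop("vqslod_fail_frac must lie in [0, 1)")
  }
  subpop_effects <- rep_len(as.numeric(subpop_effects), k_subpops)

  structure(list(
    n_per_center = n_per_center,
    n_variants = as.integer(n_variants),
    k_subpops = as.integer(k_subpops),
    fst = fst,
    ancestral_maf_range = ancestral_maf_range,
    prevalence = prevalence,
    n_causal = n_causal,
    causal_or = causal_or,
    causal_maf = causal_maf,
    n_biased = n_biased,
    c_biased = c_biased,
    biased_kit = biased_kit,
    mean_depth = mean_depth[KIT_LEVELS],
    depth_dispersion = depth_dispersion,
    base_error = base_error,
    min_call_depth = as.integer(min_call_depth),
    transition_prob = transition_prob,
    vqslod_fail_frac = vqslod_fail_frac,
    subpop_effects = subpop_effects,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", sum(x$n_per_center), "samples (",
      paste(sprintf("%s=%d", names(x$n_per_center), x$n_per_center),
            collapse = ", "),
      "), ", x$n_variants, " variants\n", sep = "")
  cat("  subpops:", x$k_subpops, " F_ST:", x$fst,
      " prevalence:", x$prevalence, "\n")
  cat("  causal:", x$n_causal, " biased:", x$n_biased,
      sprintf(" (c=%.3g in %s)", x$c_biased, x$biased_kit), "\n")
  cat("  depth:", paste(sprintf("%s=%g", names(x$mean_depth), x$mean_depth),
                        collapse = ", "),
      " eps:", x$base_error, " seed:", x$seed, "\n")
  invisible(x)
}
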