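#' varbatch: variant-level batch effect diagnostics
#'
#' Tools to simulate, detect and adjudicate hidden variant-level batch
#' effects (capture-kit differences in genotype quality and alternative
#' allele fraction) in case/control sequencing association studies.
#'
#' @keywords internal
#' @importFrom stats dbinom rbinom rnbinom rnorm runif rbeta plogis qlogis
#'   glm.fit binomial pnorm pchisq qchisq kmeans quantile median var sd cor
#'   complete.cases setNames uniroot binom.test model.matrix dist
#' @importFrom mclust Mclust mclustBIC
#' @importFrom utils write.table read.table head
"_PACKAGE"

# Centers and the hard-wired center -> capture-kit map of the study design
# (one center on kit A, two centers on kit B).
CENTER_LEVELS <- c("C1", "C2", "C3")
KIT_LEVELS <- c("KitA", "KitB")
CENTER_KIT_MAP <- c(C1 = "KitA", C2 = "KitB", C3 = "KitB")

#' Capture kit implied by sequencing center
#'
#' The study design confounds capture kit with sequencing center: center C1
#' uses KitA while centers C2 and C3 use KitB. Kit is therefore a
#' deterministic function of center.
#'
#' @param center character vector of center labels (`"C1"`, `"C2"`, `"C3"`).
#' @return character vector of kit labels (`"KitA"` or `"KitB"`).
#' @export
center_to_kit <- function(center) {
  bad <- setdiff(unique(center), CENTER_LEVELS)
  if (length(bad) > 0) {
    stop("unknown center label(s): ", paste(bad, collapse = ", "))
  }
  unname(CENTER_KIT_MAP[center])
}

#' Published center census of the motivating exome study
#'
#' Per-center sample counts of the cohort that motivated this package
#' (three sequencing centers, two capture kits), used to parameterize
#' study-scale configurations and bookkeeping checks.
#'
#' @return data.frame with columns `center`, `kit`, `n_samples`.
#' @export
adsp_design <- function() {
  data.frame(
    center = CENTER_LEVELS,
    kit = unname(CENTER_KIT_MAP[CENTER_LEVELS]),
    n_samples = c(4427L, 3260L, 2217L),
    stringsAsFactors = FALSE
  )
}

#' Fold an allele frequency to the minor allele
#'
#' @param f numeric vector of alternative-allele frequencies in \[0, 1\].
#' @return frequencies folded into \[0, 0.5\].
#' @export
fold_maf <- function(f) {
  pmin(f, 1 - f)
}

#' Genomic inflation factor
#'
#' Median chi-square statistic (from two-sided p-values, 1 df) divided by
#' its null expectation, `qchisq(0.5, 1)`. Values well above 1 indicate
#' confounding or systematic test miscalibration.
#'
#' @param p numeric vector of p-values; `NA`s are dropped.
#' @return lambda_GC, a single number.
#' @export
lambda_gc <- function(p) {
  p <- p[is.finite(p)]
  if (length(p) == 0) return(NA_real_)
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}

# Derive a deterministic sub-seed for a named stage from a master seed.
# Keeps every stage's stream reproducible from one configured seed while
# decoupling stages from each other. Result stays below 2^31.
stage_seed <- function(seed, stage) {
  offs <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) + offs * 10007L) %% 2147483629L
}

# phred-scale an error probability, capped (VCF GQ convention)
phred <- function(p_err, cap = 99L) {
  q <- -10 * log10(pmax(p_err, 1e-300))
  as.integer(pmin(floor(q), cap))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
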