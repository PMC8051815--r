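#' Simulate cohort ground truth: genotypes, phenotype, batch assignment
#'
#' Draws a synthetic case/control cohort under the Balding-Nichols model of
#' population substructure. Subpopulation allele frequencies are drawn from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` around the ancestral frequency `p`
#' (degenerating to `p` at `F = 0`); genotypes are drawn in
#' Hardy-Weinberg proportions within each subpopulation. The case/control
#' phenotype follows an additive logistic model over the causal variants
#' (plus optional subpopulation offsets); its intercept is solved by root
#' finding so the expected case fraction matches the configured prevalence.
#' Samples are assigned to centers by the configured counts; capture kit is
#' the deterministic function of center.
#'
#' @param config a [sim_config()] object.
#' @return list with elements `truth` (class `truth_table`: genotype dosage
#'   matrix `variants x samples`, per-variant table with causal log-odds and
#'   per-kit capture efficiencies, subpopulation frequency matrix,
#'   per-sample subpopulation, phenotype-model intercept) and `samples`
#'   (data.frame of sample records: id, center, kit, sex, phenotype, age,
#'   major-locus covariate, subpopulation).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "cohort"))
  m <- config$n_variants
  k <- config$k_subpops
  n <- sum(config$n_per_center)

  # variant scaffold: one chromosome, evenly spaced biallelic SNPs,
  # transition/transversion mix controlled by transition_prob
  is_ti <- runif(m) < config$transition_prob
  ref <- sample(c("A", "C", "G", "T"), m, replace = TRUE)
  ti_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv_choices <- list(A = c("C", "T"), G = c("C", "T"),
                     C = c("A", "G"), T = c("A", "G"))
  alt <- ifelse(is_ti, ti_map[ref],
                vapply(ref, function(r) sample(tv_choices[[r]], 1L), ""))
  variants <- data.frame(
    chrom = "1",
    pos = seq_len(m) * 10000L,
    ref = ref, alt = unname(alt),
    stringsAsFactors = FALSE
  )

  p0 <- runif(m, config$ancestral_maf_range[1], config$ancestral_maf_range[2])
  causal_idx <- if (config$n_causal > 0) {
    sort(sample.int(m, config$n_causal))
  } else integer(0)
  if (!is.null(config$causal_maf)) p0[causal_idx] <- config$causal_maf
  beta <- numeric(m)
  beta[causal_idx] <- log(config$causal_or)

  # biased variants: causal first (the confounded-signal scenario), then
  # non-causal fill
  biased_idx <- integer(0)
  if (config$n_biased > 0) {
    take_causal <- utils::head(causal_idx, config$n_biased)
    extra <- config$n_biased - length(take_causal)
    pool <- setdiff(seq_len(m), causal_idx)
    biased_idx <- sort(c(take_causal,
                         if (extra > 0) sample(pool, extra) else integer(0)))
  }
  c_kit <- matrix(1, nrow = m, ncol = 2, dimnames = list(NULL, KIT_LEVELS))
  c_kit[biased_idx, config$biased_kit] <- config$c_biased

  # Balding-Nichols subpopulation frequencies
  subpop_freq <- matrix(p0, nrow = m, ncol = k)
  if (config$fst > 0) {
    a <- p0 * (1 - config$fst) / config$fst
    b <- (1 - p0) * (1 - config$fst) / config$fst
    for (j in seq_len(k)) {
      subpop_freq[, j] <- rbeta(m, a, b)
    }
    # keep sites polymorphic overall
    subpop_freq <- pmin(pmax(subpop_freq, 1e-4), 1 - 1e-4)
  }

  centers <- rep(CENTER_LEVELS, times = config$n_per_center)
  subpop <- sample.int(k, n, replace = TRUE)
  sex <- sample(c("F", "M"), n, replace = TRUE)

  # genotypes: HWE within subpopulation
  geno <- matrix(0L, nrow = m, ncol = n)
  for (j in seq_len(k)) {
    cols <- which(subpop == j)
    if (length(cols) == 0) next
    geno[, cols] <- matrix(
      rbinom(m * length(cols), 2L, rep(subpop_freq[, j], length(cols))),
      nrow = m
    )
  }

  # phenotype: additive logistic model, intercept solved for prevalence
  score <- if (length(causal_idx) > 0) {
    drop(crossprod(geno[causal_idx, , drop = FALSE], beta[causal_idx]))
  } else numeric(n)
  score <- score + config$subpop_effects[subpop]
  f <- function(a) mean(plogis(a + score)) - config$prevalence
  if (f(-30) > 0 || f(30) < 0) {
    stop("target prevalence unattainable under the configured effects")
  }
  alpha <- uniroot(f, c(-30, 30), tol = 1e-10)$root
  phenotype <- ifelse(runif(n) < plogis(alpha + score), "case", "control")
  # age confounds with disease status by design (cases older), so models
  # adjusting for age lose the genetic signal
  age <- round(ifelse(phenotype == "case", rnorm(n, 80, 6), rnorm(n, 71, 6)))

  major_locus <- if (length(causal_idx) > 0) causal_idx[1] else NA_integer_
  apoe_cov <- if (is.na(major_locus)) rep(NA_integer_, n) else geno[major_locus, ]

  variants$ancestral_maf <- p0
  variants$causal <- seq_len(m) %in% causal_idx
  variants$beta <- beta
  variants$biased <- seq_len(m) %in% biased_idx
  variants$c_KitA <- c_kit[, "KitA"]
  variants$c_KitB <- c_kit[, "KitB"]

  samples <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    center = centers,
    kit = center_to_kit(centers),
    sex = sex,
    phenotype = phenotype,
    age = age,
    apoe_cov = apoe_cov,
    subpop = subpop,
    stringsAsFactors = FALSE
  )

  truth <- structure(list(
    genotypes = geno,
    variants = variants,
    subpop_freq = subpop_freq,
    subpop = subpop,
    alpha = alpha,
    major_locus = major_locus
  ), class = "truth_table")

  list(truth = truth, samples = samples)
}

#' @export
print.truth_table <- function(x, ...) {
  cat("truth_table:", nrow(x$genotypes), "variants x",
      ncol(x$genotypes), "samples;",
      sum(x$variants$causal), "causal,", sum(x$variants$biased), "biased\n")
  invisible(x)
}

# per-read alternative-allele probability under capture efficiency c:
# ref templates weighted 1, alt templates weighted c, base error eps
alt_read_prob <- function(g, c_eff, eps) {
  ifelse(g == 0L, eps,
         ifelse(g == 1L, (c_eff * (1 - eps) + eps) / (1 + c_eff),
                1 - eps))
}

#' Simulate read-level calls from cohort truth
#'
#' Per sample and variant, total depth is negative binomial with the kit's
#' mean depth scaled by the capture weight of the genotype (ref and alt
#' templates are captured with relative weights 1 and `c`, so depth scales
#' by 1, (1+c)/2 and c for dosage 0, 1, 2). Each read supports the
#' alternative allele with probability `eps` (hom-ref),
#' `(c(1-eps) + eps) / (1+c)` (het) or `1-eps` (hom-alt). Genotypes are
#' re-called by maximum binomial likelihood over expected alternative-read
#' fractions `{eps, 1/2, 1-eps}` with a flat prior; GQ is the phred-scaled
#' probability the call is wrong (1 - posterior), capped at 99. Calls with
#' depth below `min_call_depth` are set missing. A positive VQSLOD-style
#' site score is drawn for every site unless `vqslod_fail_frac` injects
#' failures.
#'
#' When the biased kit's capture efficiency is small, heterozygotes in that
#' kit lose most alternative reads and are mis-called homozygous reference
#' (allele dropout), which is the mechanism this package exists to detect.
#'
#' @param truth `truth_table` from [simulate_cohort()].
#' @param samples sample records from [simulate_cohort()].
#' @param config the [sim_config()] used to generate them.
#' @return a `call_set` (see [call_set()]).
#' @export
simulate_calls <- function(truth, samples, config) {
  stopifnot(inherits(truth, "truth_table"), inherits(config, "sim_config"))
  if (ncol(truth$genotypes) != nrow(samples)) {
    stop("truth and samples are inconsistent")
  }
  set.seed(stage_seed(config$seed, "calls"))
  m <- nrow(truth$genotypes)
  n <- nrow(samples)
  eps <- config$base_error
  theta <- config$depth_dispersion
  d_kit <- config$mean_depth[samples$kit]
  kitA <- samples$kit == "KitA"

  gt <- matrix(NA_integer_, m, n)
  ad_ref <- matrix(0L, m, n)
  ad_alt <- matrix(0L, m, n)
  dp <- matrix(0L, m, n)
  gq <- matrix(NA_integer_, m, n)

  chunk <- max(1L, min(m, as.integer(ceiling(2e6 / n))))
  for (start in seq(1L, m, by = chunk)) {
    idx <- start:min(start + chunk - 1L, m)
    g <- truth$genotypes[idx, , drop = FALSE]
    cv <- ifelse(rep(kitA, each = length(idx)),
                 truth$variants$c_KitA[idx],
                 truth$variants$c_KitB[idx])
    cmat <- matrix(cv, nrow = length(idx))
    w <- 1 + (cmat - 1) * g / 2           # capture weight per genotype
    mu <- sweep(w, 2, d_kit, `*`)
    depth <- matrix(rnbinom(length(mu), size = theta, mu = mu),
                    nrow = length(idx))
    pi_alt <- alt_read_prob(g, cmat, eps)
    alt <- matrix(rbinom(length(depth), depth, pi_alt), nrow = length(idx))

    # flat-prior ML caller over expected alt fractions {eps, 1/2, 1-eps}
    l0 <- dbinom(alt, depth, eps, log = TRUE)
    l1 <- dbinom(alt, depth, 0.5, log = TRUE)
    l2 <- dbinom(alt, depth, 1 - eps, log = TRUE)
    call <- matrix(0L, nrow(l0), ncol(l0))
    call[l1 > l0] <- 1L
    call[l2 > pmax(l0, l1)] <- 2L
    lmax <- pmax(l0, l1, l2)
    denom <- exp(l0 - lmax) + exp(l1 - lmax) + exp(l2 - lmax)
    lcall <- l0
    lcall[call == 1L] <- l1[call == 1L]
    lcall[call == 2L] <- l2[call == 2L]
    post <- exp(lcall - lmax) / denom
    q <- matrix(phred(1 - post), nrow(l0), ncol(l0))

    miss <- depth < config$min_call_depth
    call[miss] <- NA_integer_
    q[miss] <- NA_integer_

    storage.mode(depth) <- "integer"
    storage.mode(alt) <- "integer"
    gt[idx, ] <- call
    gq[idx, ] <- q
    dp[idx, ] <- depth
    ad_alt[idx, ] <- alt
    ad_ref[idx, ] <- depth - alt
  }

  vqslod <- round(abs(rnorm(m, mean = 5, sd = 2)) + 0.01, 3)
  if (config$vqslod_fail_frac > 0) {
    nf <- round(config$vqslod_fail_frac * m)
    if (nf > 0) {
      fail <- sample.int(m, nf)
      vqslod[fail] <- -round(abs(rnorm(nf, mean = 2, sd = 1)) + 0.01, 3)
    }
  }

  variants <- truth$variants[, c("chrom", "pos", "ref", "alt")]
  variants$vqslod <- vqslod
  call_set(variants, samples$sample_id, gt, ad_ref, ad_alt, dp, gq)
}
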