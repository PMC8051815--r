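# Independent oracles and tiny fixture builders shared across the suite.

# --- HWE enumeration oracle ------------------------------------------------
# Exact conditional distribution of heterozygote counts given allele counts,
# built by the Levene/Haldane probability recurrence (ratio of successive
# heterozygote probabilities), independent of the closed-form implementation.
oracle_hwe_p <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  rare <- min(2L * n_AA + n_Aa, 2L * n_aa + n_Aa)
  if (rare == 0L) return(1)
  hs <- seq.int(rare %% 2L, rare, by = 2L)
  pr <- numeric(length(hs))
  pr[1] <- 1
  if (length(hs) > 1) {
    for (i in seq_len(length(hs) - 1L)) {
      h <- hs[i]
      # P(h+2) / P(h) for the conditional heterozygote distribution
      ratio <- 4 * ((rare - h) / 2) * (n - (rare + h) / 2) /
        ((h + 2) * (h + 1))
      pr[i + 1L] <- pr[i] * ratio
    }
  }
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_Aa, hs)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-10)]))
}

# --- Newton-Raphson logistic oracle ---------------------------------------
# Textbook Newton iteration on the log-likelihood, written without glm
# machinery; returns the coefficient vector for design matrix x (with
# intercept column already included).
oracle_logistic <- function(x, y, max_iter = 100, tol = 1e-12) {
  beta <- rep(0, ncol(x))
  for (it in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    mu <- 1 / (1 + exp(-eta))
    grad <- drop(crossprod(x, y - mu))
    w <- mu * (1 - mu)
    hess <- crossprod(x * w, x)
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

# --- tiny call_set builders ------------------------------------------------
# Hand-sized call set from explicit matrices, with sensible AD/DP/GQ filled
# in from the genotype when not given.
make_calls <- function(gt, vqslod = NULL, pos = NULL, ref = NULL, alt = NULL,
                       dp_val = 30L, chrom = "1") {
  gt <- as.matrix(gt)
  dimnames(gt) <- NULL
  m <- nrow(gt); n <- ncol(gt)
  storage.mode(gt) <- "integer"
  dp <- matrix(dp_val, m, n)
  dp[is.na(gt)] <- 0L
  ad_alt <- matrix(0L, m, n)
  ad_alt[!is.na(gt)] <- as.integer(round(dp[!is.na(gt)] * gt[!is.na(gt)] / 2))
  ad_ref <- dp - ad_alt
  gq <- matrix(99L, m, n)
  gq[is.na(gt)] <- NA_integer_
  variants <- data.frame(
    chrom = chrom,
    pos = pos %||% (seq_len(m) * 1000L),
    ref = ref %||% rep("A", m),
    alt = alt %||% rep("G", m),
    vqslod = vqslod %||% rep(5, m),
    stringsAsFactors = FALSE
  )
  call_set(variants, sprintf("S%03d", seq_len(n)), gt, ad_ref, ad_alt, dp, gq)
}

make_samples <- function(calls, center = NULL, phenotype = NULL, sex = NULL) {
  n <- n_samples(calls)
  center <- center %||% rep(c("C1", "C2", "C3"), length.out = n)
  data.frame(
    sample_id = calls$samples,
    center = center,
    kit = center_to_kit(center),
    sex = sex %||% rep(c("F", "M"), length.out = n),
    phenotype = phenotype %||% rep(c("case", "control"), length.out = n),
    apoe_cov = rep(0L, n),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
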