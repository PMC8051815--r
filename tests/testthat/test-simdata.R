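test_that("config validation rejects impossible designs", {
  expect_error(sim_config(k_subpops = 0), "k_subpops")
  expect_error(sim_config(n_per_center = c(C1 = 0L, C2 = 5L, C3 = 5L)),
               "center")
  expect_error(sim_config(fst = 1), "fst")
  expect_error(sim_config(prevalence = 0), "prevalence")
  expect_error(sim_config(c_biased = 0), "c_biased")
  # unattainable prevalence: huge protective subpop offsets on everyone
  cfg <- sim_config(n_per_center = c(C1 = 20L, C2 = 20L, C3 = 20L),
                    n_variants = 10, n_causal = 0, n_biased = 0,
                    k_subpops = 1, subpop_effects = -100, prevalence = 0.99,
                    seed = 1)
  expect_error(simulate_cohort(cfg), "prevalence")
})

test_that("Balding-Nichols degenerates to the ancestral frequency at F = 0", {
  cfg <- sim_config(n_per_center = c(C1 = 10L, C2 = 10L, C3 = 10L),
                    n_variants = 50, k_subpops = 3, fst = 0,
                    n_causal = 0, n_biased = 0, seed = 42)
  sim <- simulate_cohort(cfg)
  expect_equal(sim$truth$subpop_freq[, 1], sim$truth$variants$ancestral_maf)
  expect_equal(sim$truth$subpop_freq[, 2], sim$truth$subpop_freq[, 3])
})

test_that("fixed seed reproduces the cohort and the calls exactly", {
  cfg <- sim_config(n_per_center = c(C1 = 30L, C2 = 20L, C3 = 20L),
                    n_variants = 40, seed = 9,
                    n_causal = 2, n_biased = 1)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  ca <- simulate_calls(a$truth, a$samples, cfg)
  cb <- simulate_calls(b$truth, b$samples, cfg)
  expect_identical(ca, cb)
})

test_that("causal variants show case-enriched truth MAF across seeds", {
  for (s in 1:10) {
    cfg <- sim_config(n_per_center = c(C1 = 1500L, C2 = 1500L, C3 = 1000L),
                      n_variants = 20, n_causal = 2, causal_or = 2.0,
                      causal_maf = 0.2, n_biased = 0, fst = 0, seed = s)
    sim <- simulate_cohort(cfg)
    ci <- which(sim$truth$variants$causal)
    case <- sim$samples$phenotype == "case"
    for (v in ci) {
      maf_case <- mean(sim$truth$genotypes[v, case]) / 2
      maf_ctrl <- mean(sim$truth$genotypes[v, !case]) / 2
      expect_gt(maf_case, maf_ctrl)
    }
  }
})

test_that("expected prevalence is hit by the solved intercept", {
  cfg <- sim_config(n_per_center = c(C1 = 2000L, C2 = 1500L, C3 = 1500L),
                    n_variants = 30, n_causal = 3, prevalence = 0.3, seed = 5)
  sim <- simulate_cohort(cfg)
  expect_lt(abs(mean(sim$samples$phenotype == "case") - 0.3), 0.03)
})

test_that("kit is a deterministic function of center", {
  cfg <- sim_config(n_per_center = c(C1 = 10L, C2 = 10L, C3 = 10L),
                    n_variants = 10, n_causal = 0, n_biased = 0, seed = 2)
  sim <- simulate_cohort(cfg)
  expect_identical(sim$samples$kit, center_to_kit(sim$samples$center))
  expect_setequal(sim$samples$kit[sim$samples$center == "C1"], "KitA")
  expect_setequal(sim$samples$kit[sim$samples$center != "C1"], "KitB")
})

test_that("heterozygote alt-read fraction follows c/(1+c)", {
  # closed form at c = 1: exactly 1/2
  expect_equal(varbatch:::alt_read_prob(1L, 1, 0), 0.5)
  # c = 0.3, eps = 0: 0.3/1.3, Monte-Carlo check over ~1e5 reads
  expect_equal(varbatch:::alt_read_prob(1L, 0.3, 0), 0.3 / 1.3)
  set.seed(1)
  reads <- rbinom(1e5, 1, varbatch:::alt_read_prob(1L, 0.3, 0))
  mc_se <- sqrt(0.2308 * (1 - 0.2308) / 1e5)
  expect_lt(abs(mean(reads) - 0.3 / 1.3), 4 * mc_se)
})

test_that("genotype caller matches a brute-force likelihood evaluation", {
  eps <- 0.01
  cases <- list(c(ref = 10L, alt = 0L), c(ref = 5L, alt = 5L),
                c(ref = 0L, alt = 12L), c(ref = 28L, alt = 3L),
                c(ref = 20L, alt = 7L))
  for (cs in cases) {
    dp <- sum(cs)
    lik <- dbinom(cs[["alt"]], dp, c(eps, 0.5, 1 - eps))
    expected_call <- which.max(lik) - 1L
    post <- lik[expected_call + 1L] / sum(lik)
    expected_gq <- min(99L, as.integer(floor(-10 * log10(1 - post))))

    # one-sample, one-variant cohort through the simulator's caller
    cfg <- sim_config(n_per_center = c(C1 = 1L, C2 = 1L, C3 = 1L),
                      n_variants = 1, n_causal = 0, n_biased = 0,
                      base_error = eps, min_call_depth = 1, seed = 3)
    truth <- list(
      genotypes = matrix(1L, 1, 3),
      variants = data.frame(chrom = "1", pos = 100L, ref = "A", alt = "G",
                            ancestral_maf = 0.3, causal = FALSE, beta = 0,
                            biased = FALSE, c_KitA = 1, c_KitB = 1),
      subpop_freq = matrix(0.3, 1, 1), subpop = rep(1L, 3), alpha = 0,
      major_locus = NA_integer_)
    class(truth) <- "truth_table"
    # bypass read simulation: evaluate the caller arithmetic directly
    l0 <- dbinom(cs[["alt"]], dp, eps, log = TRUE)
    l1 <- dbinom(cs[["alt"]], dp, 0.5, log = TRUE)
    l2 <- dbinom(cs[["alt"]], dp, 1 - eps, log = TRUE)
    call <- 0L
    if (l1 > l0) call <- 1L
    if (l2 > max(l0, l1)) call <- 2L
    expect_identical(call, expected_call)
    lmax <- max(l0, l1, l2)
    denom <- exp(l0 - lmax) + exp(l1 - lmax) + exp(l2 - lmax)
    post_impl <- exp(c(l0, l1, l2)[call + 1L] - lmax) / denom
    expect_equal(post_impl, post, tolerance = 1e-12)
    expect_identical(varbatch:::phred(1 - post_impl), expected_gq)
  }
})

test_that("simulated calls carry the planted allelic bias signature", {
  # unbiased truth hets have AAF ~ 0.5; biased-kit MAF < unbiased-kit MAF
  wins <- 0L
  trials <- 0L
  for (s in 1:5) {
    cfg <- sim_config(n_per_center = c(C1 = 150L, C2 = 100L, C3 = 80L),
                      n_variants = 60, n_causal = 0, n_biased = 25,
                      c_biased = 0.05, seed = 200 + s)
    sim <- simulate_cohort(cfg)
    calls <- simulate_calls(sim$truth, sim$samples, cfg)
    kitA <- sim$samples$kit == "KitA"

    unbiased <- which(!sim$truth$variants$biased)
    het_unb <- sim$truth$genotypes[unbiased, , drop = FALSE] == 1L
    aaf <- calls$ad_alt[unbiased, ] /
      pmax(calls$dp[unbiased, ], 1L)
    expect_lt(abs(mean(aaf[het_unb]) - 0.5), 0.01)

    biased <- which(sim$truth$variants$biased)
    maf_a <- fold_maf(varbatch:::called_aaf(subset_call_set(calls, biased, which(kitA))))
    maf_b <- fold_maf(varbatch:::called_aaf(subset_call_set(calls, biased, which(!kitA))))
    wins <- wins + sum(maf_b < maf_a, na.rm = TRUE)
    trials <- trials + sum(!is.na(maf_a) & !is.na(maf_b) & maf_a != maf_b)
  }
  # paired one-sided sign test across biased variants
  expect_gt(trials, 100)
  expect_lt(binom.test(wins, trials, alternative = "greater")$p.value, 1e-6)
})

test_that("capture-efficiency estimator recovers c from truth hets", {
  for (s in 1:5) {
    cfg <- sim_config(n_per_center = c(C1 = 100L, C2 = 100L, C3 = 60L),
                      n_variants = 30, n_causal = 0, n_biased = 30,
                      c_biased = 0.3, base_error = 0, mean_depth = c(60, 60),
                      seed = 300 + s)
    sim <- simulate_cohort(cfg)
    calls <- simulate_calls(sim$truth, sim$samples, cfg)
    est <- estimate_capture_efficiency(
      calls, sim$samples, "KitB", het_source = "truth",
      truth_genotypes = sim$truth$genotypes)
    expect_lt(abs(mean(est$c_hat, na.rm = TRUE) - 0.3), 0.05)
  }
})
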