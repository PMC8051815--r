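test_that("logistic fit matches the independent Newton oracle", {
  set.seed(20)
  for (i in 1:100) {
    n <- sample(80:200, 1)
    k <- sample(0:3, 1)
    covar <- if (k > 0) matrix(rnorm(n * k), n, k) else NULL
    dosage <- rbinom(n, 2, runif(1, 0.1, 0.5))
    eta <- -0.2 + 0.4 * dosage +
      if (k > 0) drop(covar %*% rnorm(k, 0, 0.3)) else 0
    y <- rbinom(n, 1, plogis(eta))
    if (var(dosage) == 0 || length(unique(y)) < 2) next
    fit <- fit_logistic(y, dosage, covar)
    if (!fit$converged) next
    x <- cbind(1, dosage, covar)
    beta_oracle <- oracle_logistic(x, y)
    expect_lt(abs(fit$beta - beta_oracle[2]), 1e-6)
  }
})

test_that("no-covariate fit on a binary dosage equals the 2x2 log odds ratio", {
  # fixed fixture: carriers 30 cases / 10 controls, non-carriers 70/90
  y <- c(rep(1, 30), rep(0, 10), rep(1, 70), rep(0, 90))
  dosage <- c(rep(1, 40), rep(0, 160))
  fit <- fit_logistic(y, dosage)
  lor <- log((30 * 90) / (10 * 70))
  expect_equal(fit$beta, lor, tolerance = 1e-8)
})

test_that("degenerate dosages are flagged, not fitted", {
  y <- rep(c(0, 1), 20)
  fit <- fit_logistic(y, rep(0, 40))
  expect_false(fit$converged)
  expect_equal(fit$flag, "constant_dosage")
  expect_true(is.na(fit$p))
})

test_that("complete separation is flagged as non-converged", {
  y <- c(rep(0, 20), rep(1, 20))
  dosage <- c(rep(0, 20), rep(2, 20))
  fit <- fit_logistic(y, dosage)
  expect_false(fit$converged)
  expect_equal(fit$flag, "non_converged")
})

test_that("null p-values are uniform under permuted labels", {
  set.seed(21)
  n <- 300
  pvals <- replicate(1000, {
    dosage <- rbinom(n, 2, 0.3)
    y <- sample(rep(0:1, n / 2))
    fit_logistic(y, dosage)$p
  })
  pvals <- pvals[!is.na(pvals)]
  # dosages are discrete so duplicate p-values occur; jitter below the
  # resolution of interest to keep the KS test exact
  set.seed(1)
  pvals <- pvals * (1 - 1e-9) + runif(length(pvals), 0, 1e-9)
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("type-I error of the per-variant test is calibrated", {
  err <- numeric(3)
  for (s in 1:3) {
    set.seed(700 + s)
    n <- 800
    y <- rbinom(n, 1, 0.5)
    covar <- matrix(rnorm(n * 2), n, 2)
    p <- replicate(5000, {
      fit_logistic(y, rbinom(n, 2, runif(1, 0.05, 0.5)), covar)$p
    })
    err[s] <- mean(p < 0.05, na.rm = TRUE)
  }
  expect_lt(abs(mean(err) - 0.05), 0.01)
})

test_that("causal variants reach exome-wide significance at study power", {
  hits <- 0L
  for (s in 1:5) {
    set.seed(800 + s)
    n <- 4000
    dosage <- rbinom(n, 2, 0.2)
    y <- rbinom(n, 1, plogis(qlogis(0.5) + log(2) * (dosage - mean(dosage))))
    fit <- fit_logistic(y, dosage)
    if (fit$p < 3.0e-7) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("run_association honours strata and drops constant covariates", {
  cfg <- sim_config(n_per_center = c(C1 = 120L, C2 = 90L, C3 = 70L),
                    n_variants = 30, n_causal = 2, n_biased = 0, seed = 31)
  sim <- simulate_cohort(cfg)
  calls <- simulate_calls(sim$truth, sim$samples, cfg)

  full <- run_association(calls, sim$samples)
  expect_equal(nrow(full), 30L)
  expect_true(all(full$p > 0 & full$p <= 1, na.rm = TRUE))
  expect_true(all(full$maf_case <= 0.5 & full$maf_ctrl <= 0.5, na.rm = TRUE))

  # duplicate run is identical (determinism)
  full2 <- run_association(calls, sim$samples)
  expect_identical(full, full2)

  # within C1 the center covariate is constant: the fit must still work and
  # the design reduces to intercept + dosage
  c1 <- run_association(calls, sim$samples, stratum = "C1")
  expect_equal(unique(c1$stratum), "C1")
  expect_true(all(is.finite(c1$beta) | !c1$converged))

  covar <- varbatch:::build_covariates(
    sim$samples[sim$samples$center == "C1", ], model_spec("M1"), NULL)
  expect_null(covar)
})

test_that("model specs expose the published covariate sets", {
  expect_equal(model_spec("M1")$covariates, c("center", "pcs"))
  expect_true(all(c("sex", "apoe_cov") %in% model_spec("M2")$covariates))
  expect_true("age" %in% model_spec("M3")$covariates)
  # stratified single-class error
  cfg <- sim_config(n_per_center = c(C1 = 20L, C2 = 20L, C3 = 20L),
                    n_variants = 5, n_causal = 0, n_biased = 0, seed = 1)
  sim <- simulate_cohort(cfg)
  calls <- simulate_calls(sim$truth, sim$samples, cfg)
  sim$samples$phenotype[sim$samples$center == "C1"] <- "case"
  expect_error(run_association(calls, sim$samples, stratum = "C1"),
               "phenotype classes")
})

test_that("Bonferroni threshold arithmetic", {
  expect_equal(bonferroni_threshold(1, 0.05), 0.05)
  expect_equal(bonferroni_threshold(2000, 0.05), 2.5e-5)
  n <- 12345
  expect_equal(bonferroni_threshold(2 * n), bonferroni_threshold(n) / 2)
  expect_error(bonferroni_threshold(0), "n_tests")
})

test_that("batch-exclusive flags follow the definition", {
  tab <- function(ids, p, flag = "ok") {
    data.frame(variant_id = ids, p = p, flag = flag,
               stringsAsFactors = FALSE)
  }
  full <- tab(c("v1", "v2", "v3", "v4"), c(1e-10, 1e-10, 1e-3, 1e-10))
  kitA <- tab(c("v1", "v2", "v3", "v4"), c(1e-9, 1e-5, 0.5, NA),
              flag = c("ok", "ok", "ok", "constant_dosage"))
  kitB <- tab(c("v1", "v2", "v3", "v4"), c(0.6, 1e-5, 0.9, 1e-9))
  fl <- flag_batch_exclusive(full, kitA, kitB, threshold = 1e-7,
                             stratum_threshold = 1e-4)
  expect_equal(fl$flag, c("exclusive_KitA",  # A sig, B null
                          "concordant",      # both strata at 1e-5 < 1e-4
                          "not_significant", # full p above threshold
                          "exclusive_KitB")) # A constant dosage -> no evidence
  # a variant absent from a stratum table is indeterminate
  expect_message(
    fl2 <- flag_batch_exclusive(full, kitA[-1, ], kitB, threshold = 1e-7),
    "indeterminate")
  expect_equal(fl2$flag[1], "indeterminate")
})

test_that("PC covariates deflate confounding-driven inflation", {
  set.seed(55)
  n_pp <- 400
  m <- 1500
  fst <- 0.1
  p0 <- runif(m, 0.1, 0.5)
  freq <- sapply(1:2, function(j)
    rbeta(m, p0 * (1 - fst) / fst, (1 - p0) * (1 - fst) / fst))
  g <- cbind(matrix(rbinom(m * n_pp, 2, rep(freq[, 1], n_pp)), m),
             matrix(rbinom(m * n_pp, 2, rep(freq[, 2], n_pp)), m))
  pop <- rep(0:1, each = n_pp)
  y <- rbinom(2 * n_pp, 1, plogis(-0.6 + 1.2 * pop))
  pca <- suppressMessages(genotype_pca(g))
  pcs <- pca$vectors[, 1:2]

  p_no <- vapply(seq_len(m), function(i) fit_logistic(y, g[i, ])$p, 0)
  p_pc <- vapply(seq_len(m), function(i) fit_logistic(y, g[i, ], pcs)$p, 0)
  l_no <- lambda_gc(p_no)
  l_pc <- lambda_gc(p_pc)
  expect_gt(l_no, 1.2)
  expect_lt(l_pc, l_no)
  expect_lt(abs(l_pc - 1), 0.15)
})
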