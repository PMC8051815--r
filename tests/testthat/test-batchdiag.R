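test_that("per-variant per-kit metrics: arithmetic on a tiny fixture", {
  # 1 variant, 2 samples, one per kit: het AD=(5,5) -> AAF 0.5
  gt <- matrix(c(1L, 1L), 1, 2)
  calls <- make_calls(gt, dp_val = 10L)
  samples <- make_samples(calls, center = c("C1", "C2"))
  m <- suppressMessages(per_variant_batch_metrics(calls, samples))
  expect_equal(m$mean_aaf_KitA, 0.5)
  expect_equal(m$mean_aaf_KitB, 0.5)
  expect_equal(m$log2_aaf, 0)

  # KitA mean AAF 0.5 vs KitB 0.125 -> log2 ratio 2
  calls$ad_alt[1, 2] <- 1L
  calls$ad_ref[1, 2] <- 7L
  calls$dp[1, 2] <- 8L
  m2 <- suppressMessages(per_variant_batch_metrics(calls, samples))
  expect_equal(m2$log2_aaf, 2)
})

test_that("aaf_mode controls the averaging set", {
  # two KitB samples: a carrier (AAF 0.5) and a zero-alt hom-ref
  gt <- matrix(c(1L, 1L, 0L), 1, 3)
  calls <- make_calls(gt, dp_val = 10L)
  samples <- make_samples(calls, center = c("C1", "C2", "C3"))
  m_car <- suppressMessages(
    per_variant_batch_metrics(calls, samples, aaf_mode = "carriers"))
  m_all <- suppressMessages(
    per_variant_batch_metrics(calls, samples, aaf_mode = "all"))
  expect_equal(m_car$mean_aaf_KitB, 0.5)       # hom-ref has no alt reads
  expect_equal(m_all$mean_aaf_KitB, 0.25)      # (0.5 + 0)/2
})

test_that("biased-kit mean AAF among true hets matches c/(1+c)", {
  cfg <- sim_config(n_per_center = c(C1 = 150L, C2 = 150L, C3 = 100L),
                    n_variants = 40, n_causal = 0, n_biased = 40,
                    c_biased = 0.3, base_error = 0, min_call_depth = 1,
                    seed = 44)
  sim <- simulate_cohort(cfg)
  calls <- simulate_calls(sim$truth, sim$samples, cfg)
  kitB <- sim$samples$kit == "KitB"
  het <- sim$truth$genotypes[, kitB, drop = FALSE] == 1L
  p_hat <- sum(calls$ad_alt[, kitB][het]) / sum(calls$dp[, kitB][het])
  p_exp <- 0.3 / 1.3
  mc_se <- sqrt(p_exp * (1 - p_exp) / sum(calls$dp[, kitB][het]))
  expect_lt(abs(p_hat - p_exp), 4 * mc_se)
})

test_that("tail partition: counts, degenerate ties and union rule", {
  set.seed(12)
  mk <- function(x) {
    data.frame(variant_id = paste0("v", seq_along(x)),
               log2_gq = x, log2_dp = x, log2_aaf = x,
               stringsAsFactors = FALSE)
  }
  x <- sample(seq(-2, 2, length.out = 100))
  tl <- partition_tails(mk(x))
  expect_equal(sum(tl$aaf_tail == "left5"), 5L)
  expect_equal(sum(tl$aaf_tail == "middle90"), 90L)
  expect_equal(sum(tl$aaf_tail == "right5"), 5L)
  expect_equal(sum(tl$any_tail), 10L)   # same variants in all three metrics

  # all ratios identical: zero-width tails, everything middle
  tl2 <- partition_tails(mk(rep(1.5, 60)))
  expect_true(all(tl2$aaf_tail == "middle90"))
  expect_false(any(tl2$any_tail))

  # union rule: a variant in the tail of one metric only is still any_tail
  df <- mk(x)
  df$log2_gq <- 0
  df$log2_dp <- 0
  df$log2_gq[1] <- 99
  tl3 <- partition_tails(df)
  expect_true(tl3$any_tail[1])
  expect_error(partition_tails(mk(c(rep(NA, 90), rnorm(10)))), ">= 20")
})

test_that("planted biased variants land in the AAF ratio tail", {
  hits <- 0L
  for (s in 1:5) {
    cfg <- sim_config(n_per_center = c(C1 = 200L, C2 = 150L, C3 = 100L),
                      n_variants = 400, n_causal = 0, n_biased = 20,
                      seed = 900 + s)
    sim <- simulate_cohort(cfg)
    calls <- simulate_calls(sim$truth, sim$samples, cfg)
    met <- suppressMessages(per_variant_batch_metrics(calls, sim$samples))
    tl <- partition_tails(met)
    biased <- which(sim$truth$variants$biased)
    hits <- hits + sum(tl$aaf_tail[biased] != "middle90", na.rm = TRUE)
  }
  expect_gte(hits / (5 * 20), 0.9)
})

test_that("kit-random subsets show no PCA separation; constructed ones do", {
  for (s in 1:5) {
    set.seed(1000 + s)
    g <- matrix(rbinom(60 * 200, 2, 0.3), 60, 200)
    storage.mode(g) <- "integer"
    calls <- make_calls(g)
    centers <- sample(rep(c("C1", "C2", "C3"), length.out = 200))
    samples <- make_samples(calls, center = centers)
    s0 <- subset_pca_separation(calls, samples, seq_len(60))
    expect_lt(abs(s0), 0.05)
  }

  # kit-exclusive genotype pattern: KitA samples carry alt, KitB never
  set.seed(2)
  centers <- rep(c("C1", "C2", "C3"), length.out = 200)
  kitA <- center_to_kit(centers) == "KitA"
  g <- matrix(0L, 30, 200)
  g[, kitA] <- matrix(rbinom(30 * sum(kitA), 2, 0.4), 30)
  noise <- matrix(rbinom(20 * 200, 2, 0.3), 20, 200)
  storage.mode(noise) <- "integer"
  calls <- make_calls(rbind(g, noise))
  samples <- make_samples(calls, center = centers)
  s1 <- subset_pca_separation(calls, samples, 1:30)
  expect_gt(s1, 0.5)
})

test_that("bimodality detection: single Gaussian vs well-separated mixture", {
  set.seed(13)
  single <- rnorm(500, -1, 0.6)
  fit1 <- fit_aaf_bimodality(single)
  expect_false(fit1$bimodal)
  expect_equal(sum(fit1$weights), 1, tolerance = 1e-8)

  mix <- c(rnorm(350, -1, 0.5), rnorm(150, -6, 0.5))
  fit2 <- fit_aaf_bimodality(mix)
  expect_true(fit2$bimodal)
  expect_lt(abs(fit2$means[1] - (-6)), 0.5)
  expect_lt(abs(fit2$means[2] - (-1)), 0.5)
  expect_equal(sum(fit2$weights), 1, tolerance = 1e-8)

  expect_message(fit_aaf_bimodality(c(mix, NA, Inf)), "2 non-finite")
  expect_error(fit_aaf_bimodality(rnorm(10)), ">= 50")
})

test_that("MAF concordance picks the kit closer to the reference", {
  # worked example from the motivating study's table: winner is KitA
  km <- data.frame(variant_id = c("a", "b"),
                   maf_KitA = c(0.056, 0.1),
                   maf_KitB = c(0.006, 0.1),
                   stringsAsFactors = FALSE)
  ref <- c(a = 0.0906, b = 0.3)
  cc <- maf_concordance(km, ref)
  expect_equal(cc$per_variant$winner, c("KitA", "none"))
  expect_equal(unname(cc$counts["KitA"]), 1L)
  expect_equal(unname(cc$counts["none"]), 1L)

  # variants absent from the reference are skipped and counted
  km2 <- rbind(km, data.frame(variant_id = "zzz", maf_KitA = 0.1,
                              maf_KitB = 0.2))
  expect_message(cc2 <- maf_concordance(km2, ref), "skipped")
  expect_equal(cc2$n_skipped, 1L)
})

test_that("concordance winners split evenly in unbiased simulations", {
  # equal kit sizes: with unequal cohorts the larger kit wins systematically
  # through smaller sampling error alone
  cfg <- sim_config(n_per_center = c(C1 = 300L, C2 = 180L, C3 = 120L),
                    n_variants = 600, n_causal = 0, n_biased = 0, seed = 77)
  sim <- simulate_cohort(cfg)
  calls <- simulate_calls(sim$truth, sim$samples, cfg)
  ref <- setNames(fold_maf(rowMeans(sim$truth$subpop_freq)),
                  variant_key(calls))
  cc <- maf_concordance(kit_control_maf(calls, sim$samples), ref)
  expect_gt(cc$sign_test_p, 0.01)
})

test_that("capture-efficiency estimator algebra", {
  # AAF 0.5 -> c = 1; AAF 1/3 -> c = 0.5
  gt <- matrix(1L, 2, 2)
  calls <- make_calls(gt, dp_val = 30L)
  calls$ad_alt[2, ] <- 10L
  calls$ad_ref[2, ] <- 20L
  samples <- make_samples(calls, center = c("C1", "C2"))
  for (kit in c("KitA", "KitB")) {
    est <- estimate_capture_efficiency(calls, samples, kit)
    expect_equal(est$c_hat, c(1, 0.5))
    expect_equal(est$n_het, c(1L, 1L))
  }
  # no carriers -> undefined
  calls$gt[] <- 0L
  est0 <- estimate_capture_efficiency(calls, samples, "KitA")
  expect_true(all(is.na(est0$c_hat)))
})

test_that("biased-kit GQ runs below unbiased-kit GQ at planted variants", {
  wins <- 0L; total <- 0L
  for (s in 1:3) {
    cfg <- sim_config(n_per_center = c(C1 = 200L, C2 = 150L, C3 = 100L),
                      n_variants = 200, n_causal = 0, n_biased = 20,
                      causal_maf = NULL, seed = 1100 + s)
    sim <- simulate_cohort(cfg)
    calls <- simulate_calls(sim$truth, sim$samples, cfg)
    met <- suppressMessages(per_variant_batch_metrics(calls, sim$samples))
    b <- which(sim$truth$variants$biased)
    d <- met$mean_gq_KitB[b] - met$mean_gq_KitA[b]
    wins <- wins + sum(d < 0, na.rm = TRUE)
    total <- total + sum(!is.na(d) & d != 0)
  }
  expect_lt(binom.test(wins, total, alternative = "greater")$p.value, 1e-4)
})
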