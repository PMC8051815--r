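#' Null-calibration study: no bias, no causal variants
#'
#' Simulates a cohort with neither kit bias nor causal variants at study
#' scale (2,000 samples across three centers, 20,000 variants by default),
#' runs sample QC, the association variant filters, pruned-set PCA and the
#' full-cohort additive logistic model, and measures: the per-variant
#' type-I error rate at p < 0.05; the medians of the per-variant log2 kit
#' ratios of mean GQ, DP and AAF (all expected at 0); and the kit
#' separation silhouette of the ratio-tail variant subset (expected at 0,
#' since tails of a null ratio distribution carry no batch signal).
#'
#' @param seed integer seed.
#' @param n_per_center samples per center.
#' @param n_variants variant count.
#' @return list: `type1_rate`, `log2_medians` (named gq/dp/aaf),
#'   `tail_silhouette`, `n_tests`.
#' @export
study_null_calibration <- function(seed,
                                   n_per_center = c(C1 = 800L, C2 = 700L,
                                                    C3 = 500L),
                                   n_variants = 20000L) {
  cfg <- sim_config(n_per_center = n_per_center, n_variants = n_variants,
                    n_causal = 0, n_biased = 0, seed = seed)
  sim <- simulate_cohort(cfg)
  calls <- simulate_calls(sim$truth, sim$samples, cfg)
  samples_all <- sim$samples
  rm(sim); gc(verbose = FALSE)
  sqc <- sample_qc(calls)
  calls <- subset_call_set(calls, samples = which(sqc$pass))
  samples <- samples_all[sqc$pass, , drop = FALSE]
  gc(verbose = FALSE)

  vf <- variant_filters(calls, samples$phenotype == "control")
  pruned <- build_pruned_set(calls, qc_thresholds(), vf$retained)
  pca <- suppressMessages(genotype_pca(calls, variants = pruned))
  n_pcs <- suppressWarnings(retain_pcs(pca))
  pcs <- if (n_pcs > 0) pca$vectors[, seq_len(n_pcs), drop = FALSE] else NULL
  gc(verbose = FALSE)

  assoc <- run_association(calls, samples, model_spec("M1"), "full",
                           pcs = pcs, variants = vf$retained)
  type1 <- mean(assoc$p < 0.05, na.rm = TRUE)

  met <- suppressMessages(per_variant_batch_metrics(
    calls, samples, variants = vf$retained))
  meds <- c(gq = stats::median(met$log2_gq, na.rm = TRUE),
            dp = stats::median(met$log2_dp, na.rm = TRUE),
            aaf = stats::median(met$log2_aaf, na.rm = TRUE))
  tails <- partition_tails(met)
  tail_idx <- vf$retained[tails$any_tail]
  sil <- if (length(tail_idx) >= 2) {
    subset_pca_separation(calls, samples, tail_idx)
  } else NA_real_

  list(type1_rate = type1, log2_medians = meds, tail_silhouette = sil,
       n_tests = nrow(assoc))
}

#' Planted-bias recovery study
#'
#' Runs the full pipeline on the default study conditions (two-kit
#' three-center cohort, causal risk variants of which a subset suffers
#' KitB capture bias) across several seeds, and pools: recall of
#' `exclusive_KitA` flags over planted biased variants; the fraction of
#' biased variants in the AAF ratio tails; the rate at which the unbiased
#' kit wins the reference-MAF concordance at biased variants; the
#' false-exclusive rate over causal but unbiased variants; and the
#' tail-vs-middle PCA kit-separation gap.
#'
#' @param seeds integer vector of seeds (one pipeline run each).
#' @param config_fn function(seed) returning the [sim_config()] to run
#'   (defaults to the package defaults).
#' @return list of pooled rates plus the per-seed separation gaps.
#' @export
study_bias_recovery <- function(seeds, config_fn = function(s) sim_config(seed = s)) {
  n_excl <- 0L; n_biased <- 0L
  n_tail <- 0L
  n_win <- 0L; n_conc <- 0L
  n_false <- 0L; n_causal_unb <- 0L
  gaps <- numeric(length(seeds))
  for (i in seq_along(seeds)) {
    rep <- run_pipeline(config_fn(seeds[i]),
                        strata = c("full", "KitA", "KitB"))
    tr <- rep$truth
    bid <- variant_key(tr$variants)[tr$variants$biased]
    cub <- variant_key(tr$variants)[tr$variants$causal & !tr$variants$biased]

    fl <- rep$flags
    n_excl <- n_excl + sum(fl$flag[fl$variant_id %in% bid] == "exclusive_KitA")
    n_biased <- n_biased + length(bid)
    n_false <- n_false + sum(grepl("exclusive", fl$flag[fl$variant_id %in% cub]))
    n_causal_unb <- n_causal_unb + length(cub)

    tl <- rep$tails
    n_tail <- n_tail + sum(tl$aaf_tail[tl$variant_id %in% bid] != "middle90",
                           na.rm = TRUE)

    cw <- rep$concordance$per_variant
    cwb <- cw[cw$variant_id %in% bid, ]
    n_win <- n_win + sum(cwb$winner == "KitA", na.rm = TRUE)
    n_conc <- n_conc + sum(!is.na(cwb$winner))

    gaps[i] <- rep$separation$tail - rep$separation$middle
  }
  list(
    recall_exclusive = n_excl / n_biased,
    tail_fraction = n_tail / n_biased,
    concordance_winner_rate = n_win / n_conc,
    false_exclusive_rate = if (n_causal_unb > 0) n_false / n_causal_unb else 0,
    separation_gaps = gaps,
    n_biased = n_biased
  )
}

#' Confounding-control study: genomic inflation with and without PCs
#'
#' Simulates a cohort whose phenotype is confounded with population
#' substructure (two subpopulations at F_ST = 0.1 with opposite phenotype
#' log-odds offsets, no causal variants) and contrasts the genomic
#' inflation factor of the full-cohort association scan without PC
#' covariates against the scan adjusted for the retained PCs.
#'
#' @param seed integer seed.
#' @param n_per_center samples per center.
#' @param n_variants variant count.
#' @return list: `lambda_no_pcs`, `lambda_with_pcs`, `n_pcs`, `n_tests`.
#' @export
study_confounding <- function(seed,
                              n_per_center = c(C1 = 500L, C2 = 400L,
                                               C3 = 300L),
                              n_variants = 4000L) {
  cfg <- sim_config(n_per_center = n_per_center, n_variants = n_variants,
                    k_subpops = 2, fst = 0.1,
                    subpop_effects = c(-0.6, 0.6),
                    n_causal = 0, n_biased = 0, seed = seed)
  sim <- simulate_cohort(cfg)
  calls <- simulate_calls(sim$truth, sim$samples, cfg)
  sqc <- sample_qc(calls)
  calls <- subset_call_set(calls, samples = which(sqc$pass))
  samples <- sim$samples[sqc$pass, , drop = FALSE]

  vf <- variant_filters(calls, samples$phenotype == "control")
  pruned <- build_pruned_set(calls, qc_thresholds(), vf$retained)
  pca <- suppressMessages(genotype_pca(calls, variants = pruned))
  n_pcs <- suppressWarnings(retain_pcs(pca))
  pcs <- if (n_pcs > 0) pca$vectors[, seq_len(n_pcs), drop = FALSE] else NULL

  a_no <- run_association(calls, samples, model_spec("M1"), "full",
                          pcs = NULL, variants = vf$retained)
  a_pc <- run_association(calls, samples, model_spec("M1"), "full",
                          pcs = pcs, variants = vf$retained)
  list(lambda_no_pcs = lambda_gc(a_no$p),
       lambda_with_pcs = lambda_gc(a_pc$p),
       n_pcs = n_pcs, n_tests = nrow(a_no))
}
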