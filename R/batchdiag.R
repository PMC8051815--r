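#' Per-variant per-kit quality metrics and their log2 ratios
#'
#' For every variant, the mean genotype quality (GQ) and depth (DP) across
#' the called samples of each capture kit, and the mean per-sample
#' alternative allele fraction (AAF = alt reads / total reads). The AAF
#' averaging set is controlled by `aaf_mode`: `"carriers"` (default)
#' averages over called samples with at least one alternative-supporting
#' read, which makes the statistic interpretable as per-carrier allelic
#' balance; `"all"` averages over every called sample with nonzero depth,
#' reproducing a variant-wide mean. Log2 kit ratios (KitA / KitB) are
#' defined only where both per-kit means are positive.
#'
#' @param calls a [call_set()].
#' @param samples sample records aligned with `calls$samples`.
#' @param aaf_mode `"carriers"` or `"all"`.
#' @param variants optional variant index restriction.
#' @return data.frame of class `batch_metrics`: per-kit `mean_gq`,
#'   `mean_dp`, `mean_aaf`, `n` columns (suffixed `_KitA` / `_KitB`) and
#'   `log2_gq`, `log2_dp`, `log2_aaf`.
#' @export
per_variant_batch_metrics <- function(calls, samples,
                                      aaf_mode = c("carriers", "all"),
                                      variants = NULL) {
  aaf_mode <- match.arg(aaf_mode)
  stopifnot(inherits(calls, "call_set"))
  if (!identical(calls$samples, samples$sample_id)) {
    stop("calls and samples are not aligned")
  }
  if (length(unique(samples$kit)) < 2) stop("both kits must be represented")
  vi <- variants %||% seq_len(n_variants(calls))

  # masked row means without materializing full-cohort temporaries
  safe_mean <- function(mat, mask) {
    x <- mat
    x[!mask] <- 0
    x[is.na(x)] <- 0
    n <- rowSums(mask)
    ifelse(n > 0, rowSums(x) / n, NA_real_)
  }

  out <- data.frame(variant_id = variant_key(calls)[vi],
                    stringsAsFactors = FALSE)
  for (kit in KIT_LEVELS) {
    cols <- which(samples$kit == kit)
    gt_k <- calls$gt[vi, cols, drop = FALSE]
    cc <- !is.na(gt_k)
    alt_k <- calls$ad_alt[vi, cols, drop = FALSE]
    reads_k <- calls$ad_ref[vi, cols, drop = FALSE] + alt_k
    out[[paste0("mean_gq_", kit)]] <-
      safe_mean(calls$gq[vi, cols, drop = FALSE], cc)
    out[[paste0("mean_dp_", kit)]] <-
      safe_mean(calls$dp[vi, cols, drop = FALSE], cc)
    eligible <- cc & reads_k > 0L &
      (if (aaf_mode == "carriers") alt_k >= 1L else TRUE)
    aaf_k <- alt_k / pmax(reads_k, 1L)
    out[[paste0("mean_aaf_", kit)]] <- safe_mean(aaf_k, eligible)
    out[[paste0("n_", kit)]] <- rowSums(cc)
  }
  for (metric in c("gq", "dp", "aaf")) {
    a <- out[[paste0("mean_", metric, "_KitA")]]
    b <- out[[paste0("mean_", metric, "_KitB")]]
    ratio <- ifelse(!is.na(a) & !is.na(b) & a > 0 & b > 0,
                    log2(a / b), NA_real_)
    out[[paste0("log2_", metric)]] <- ratio
  }
  n_undef <- sum(!stats::complete.cases(
    out[, c("log2_gq", "log2_dp", "log2_aaf")]))
  if (n_undef > 0) {
    message(n_undef, " variant(s) with undefined kit ratio(s)")
  }
  class(out) <- c("batch_metrics", "data.frame")
  out
}

#' Partition metric ratios into distribution tails
#'
#' Assigns each variant to `left5`, `middle90` or `right5` per metric by
#' the empirical `tail_frac` and `1 - tail_frac` quantiles (strict
#' inequalities, so a degenerate distribution has zero-width tails), and
#' marks a variant as `any_tail` when it lies in either tail of any
#' metric — the union rule used for "largest kit differences" subsets.
#'
#' @param metrics a `batch_metrics` data.frame (or any data.frame with
#'   `log2_gq`, `log2_dp`, `log2_aaf` and `variant_id`).
#' @param tail_frac tail mass per side (default 0.05).
#' @return data.frame: `variant_id`, `gq_tail`, `dp_tail`, `aaf_tail`
#'   (factors, `NA` where the ratio is undefined), `any_tail` (logical).
#' @export
partition_tails <- function(metrics, tail_frac = 0.05) {
  stopifnot(tail_frac > 0, tail_frac < 0.5)
  out <- data.frame(variant_id = metrics$variant_id, stringsAsFactors = FALSE)
  any_tail <- rep(FALSE, nrow(metrics))
  for (metric in c("gq", "dp", "aaf")) {
    x <- metrics[[paste0("log2_", metric)]]
    ok <- is.finite(x)
    if (sum(ok) < 20) {
      stop("need >= 20 variants with defined ", metric, " ratios")
    }
    lo <- stats::quantile(x[ok], tail_frac, names = FALSE)
    hi <- stats::quantile(x[ok], 1 - tail_frac, names = FALSE)
    lab <- rep(NA_character_, length(x))
    lab[ok] <- "middle90"
    lab[ok & x < lo] <- "left5"
    lab[ok & x > hi] <- "right5"
    out[[paste0(metric, "_tail")]] <-
      factor(lab, levels = c("left5", "middle90", "right5"))
    any_tail <- any_tail | (ok & lab != "middle90")
  }
  out$any_tail <- any_tail
  out
}

#' Kit separation of samples in a variant subset's PC space
#'
#' Runs genotype PCA restricted to the given variants and scores how
#' cleanly the two capture kits separate on the first two principal
#' components: the mean silhouette width of the kit labels. Values near 0
#' mean no batch structure; values well above 0 mean the subset's
#' genotypes split the cohort by kit.
#'
#' @param calls a [call_set()].
#' @param samples sample records aligned with `calls$samples`.
#' @param variant_subset integer variant indices (>= 2).
#' @return single numeric separation score.
#' @export
subset_pca_separation <- function(calls, samples, variant_subset) {
  if (length(variant_subset) < 2) stop("variant subset must have >= 2 variants")
  if (length(unique(samples$kit)) < 2) stop("both kits must be represented")
  pca <- suppressMessages(genotype_pca(calls, variants = variant_subset))
  k <- min(2L, ncol(pca$vectors))
  coords <- pc_scores(pca, k)
  lab <- as.integer(factor(samples$kit, levels = KIT_LEVELS))
  mean(cluster::silhouette(lab, stats::dist(coords))[, "sil_width"])
}

#' Two-component Gaussian mixture fit of log2 mean AAF
#'
#' Fits one- and two-component Gaussian mixtures (unequal variances, EM
#' via `mclust`) to the log2 per-variant mean alternative allele
#' fractions, and flags bimodality when the two-component model is
#' preferred by BIC, both weights are at least 0.05, and the component
#' means are separated by more than two pooled standard deviations. The
#' second, low mode is the signature of systematic alternative-allele
#' capture loss.
#'
#' @param log2_aaf numeric vector (>= 50 finite values; non-finite values
#'   are dropped with a message).
#' @return list of class `bimodality_fit`: `means` (increasing), `sds`,
#'   `weights` (sum to 1), `separation` (in pooled SD units), `bic1`,
#'   `bic2`, `bimodal` (flag), `n_used`, `n_dropped`.
#' @export
fit_aaf_bimodality <- function(log2_aaf) {
  x <- log2_aaf[is.finite(log2_aaf)]
  n_dropped <- length(log2_aaf) - length(x)
  if (n_dropped > 0) message(n_dropped, " non-finite value(s) dropped")
  if (length(x) < 50) stop("need >= 50 finite values")

  fit1 <- mclust::Mclust(x, G = 1, modelNames = "V", verbose = FALSE)
  fit2 <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  mu <- fit2$parameters$mean
  sig <- sqrt(fit2$parameters$variance$sigmasq)
  if (length(sig) == 1L) sig <- rep(sig, 2L)
  w <- fit2$parameters$pro
  ord <- order(mu)
  mu <- mu[ord]; sig <- sig[ord]; w <- w[ord]
  pooled <- sqrt(sum(w * sig^2))
  separation <- (mu[2] - mu[1]) / pooled
  # mclust BIC: larger is better
  bimodal <- fit2$bic > fit1$bic && all(w >= 0.05) && separation > 2
  structure(list(
    means = mu, sds = sig, weights = w, separation = separation,
    bic1 = fit1$bic, bic2 = fit2$bic, bimodal = bimodal,
    n_used = length(x), n_dropped = n_dropped
  ), class = "bimodality_fit")
}

#' @export
print.bimodality_fit <- function(x, ...) {
  cat(sprintf(
    "bimodality_fit: modes %.2f / %.2f (w = %.2f / %.2f), separation %.2f SD, bimodal: %s\n",
    x$means[1], x$means[2], x$weights[1], x$weights[2], x$separation,
    x$bimodal))
  invisible(x)
}

#' Per-kit control-sample minor allele frequencies
#'
#' @param calls a [call_set()].
#' @param samples sample records aligned with `calls$samples`.
#' @return data.frame: `variant_id`, `maf_KitA`, `maf_KitB` (folded,
#'   control samples only).
#' @export
kit_control_maf <- function(calls, samples) {
  stopifnot(identical(calls$samples, samples$sample_id))
  ctrl <- samples$phenotype == "control"
  out <- data.frame(variant_id = variant_key(calls), stringsAsFactors = FALSE)
  for (kit in KIT_LEVELS) {
    cols <- which(ctrl & samples$kit == kit)
    out[[paste0("maf_", kit)]] <- fold_maf(called_aaf(calls, cols))
  }
  out
}

#' Reference MAF concordance between kits
#'
#' For each variant present in the reference table, compares each kit's
#' control-sample MAF with the reference MAF by absolute distance and
#' names the closer kit the winner (ties -> `none`). The summary counts
#' winners and reports a two-sided sign test of the winner split; under no
#' kit bias the split is ~50/50, while systematic allele dropout in one
#' kit makes the other kit the consistent winner.
#'
#' @param kit_maf data.frame from [kit_control_maf()] (or any table with
#'   `variant_id`, `maf_KitA`, `maf_KitB`).
#' @param ref named numeric vector from [read_ref_maf()].
#' @return list: `per_variant` (data.frame with distances and `winner`),
#'   `counts` (KitA/KitB/none), `sign_test_p`, `n_skipped` (absent from
#'   the reference).
#' @export
maf_concordance <- function(kit_maf, ref) {
  idx <- match(kit_maf$variant_id, names(ref))
  skipped <- is.na(idx)
  if (any(skipped)) {
    message(sum(skipped), " variant(s) absent from the reference table; skipped")
  }
  df <- kit_maf[!skipped, , drop = FALSE]
  rmaf <- unname(ref[idx[!skipped]])
  d_a <- abs(df$maf_KitA - rmaf)
  d_b <- abs(df$maf_KitB - rmaf)
  winner <- ifelse(is.na(d_a) | is.na(d_b), NA_character_,
                   ifelse(d_a < d_b, "KitA", ifelse(d_b < d_a, "KitB", "none")))
  counts <- c(KitA = sum(winner == "KitA", na.rm = TRUE),
              KitB = sum(winner == "KitB", na.rm = TRUE),
              none = sum(winner == "none", na.rm = TRUE))
  n_ab <- counts[["KitA"]] + counts[["KitB"]]
  sign_p <- if (n_ab > 0) {
    stats::binom.test(counts[["KitA"]], n_ab)$p.value
  } else NA_real_
  per_variant <- data.frame(
    variant_id = df$variant_id, maf_KitA = df$maf_KitA,
    maf_KitB = df$maf_KitB, maf_ref = rmaf,
    dist_KitA = d_a, dist_KitB = d_b, winner = winner,
    stringsAsFactors = FALSE
  )
  list(per_variant = per_variant, counts = counts, sign_test_p = sign_p,
       n_skipped = sum(skipped))
}

#' Estimate allelic capture efficiency from heterozygote read balance
#'
#' Under the capture-bias model a heterozygote's expected alternative read
#' fraction is `c / (1 + c)` (error-free), so `AAF / (1 - AAF)` — i.e.
#' alt reads over ref reads — estimates `c` per carrier. The estimator is
#' the mean of that ratio over heterozygous carriers of the kit's samples;
#' carriers with zero reference reads (infinite ratio) are excluded.
#'
#' @param calls a [call_set()].
#' @param samples sample records aligned with `calls$samples`.
#' @param kit `"KitA"` or `"KitB"`.
#' @param het_source `"called"` uses called heterozygotes; `"truth"` uses
#'   a supplied truth genotype matrix.
#' @param truth_genotypes truth dosage matrix (variants x samples),
#'   required for `het_source = "truth"`.
#' @param variants optional variant index restriction.
#' @return data.frame: `variant_id`, `c_hat` (`NA` where no usable
#'   carriers), `n_het`.
#' @export
estimate_capture_efficiency <- function(calls, samples, kit,
                                        het_source = c("called", "truth"),
                                        truth_genotypes = NULL,
                                        variants = NULL) {
  het_source <- match.arg(het_source)
  stopifnot(kit %in% KIT_LEVELS,
            identical(calls$samples, samples$sample_id))
  vi <- variants %||% seq_len(n_variants(calls))
  cols <- samples$kit == kit
  het <- if (het_source == "called") {
    !is.na(calls$gt[vi, cols, drop = FALSE]) &
      calls$gt[vi, cols, drop = FALSE] == 1L
  } else {
    if (is.null(truth_genotypes)) stop("truth_genotypes required")
    truth_genotypes[vi, cols, drop = FALSE] == 1L
  }
  alt <- calls$ad_alt[vi, cols, drop = FALSE]
  ref <- calls$ad_ref[vi, cols, drop = FALSE]
  usable <- het & ref > 0L
  ratio <- ifelse(usable, alt / pmax(ref, 1L), 0)
  n_het <- rowSums(usable)
  c_hat <- ifelse(n_het > 0, rowSums(ratio) / n_het, NA_real_)
  data.frame(
    variant_id = variant_key(calls)[vi],
    c_hat = c_hat,
    n_het = n_het,
    stringsAsFactors = FALSE
  )
}
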