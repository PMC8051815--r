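#' Association model specification
#'
#' Three nested covariate models for the additive logistic association:
#' `M1` adjusts for sequencing center and the retained genotype PCs; `M2`
#' additionally for sex and the major-locus genotype covariate; `M3`
#' additionally for age. Within a single-center stratum the center
#' covariate is constant and is dropped automatically.
#'
#' @param id one of `"M1"`, `"M2"`, `"M3"`.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(id = c("M1", "M2", "M3")) {
  id <- match.arg(id)
  covars <- switch(id,
    M1 = c("center", "pcs"),
    M2 = c("center", "pcs", "sex", "apoe_cov"),
    M3 = c("center", "pcs", "sex", "apoe_cov", "age")
  )
  structure(list(id = id, covariates = covars), class = "model_spec")
}

#' Additive logistic regression for one variant
#'
#' Fits `logit P(case) = b0 + beta * dosage + covariates` by iteratively
#' reweighted least squares (tolerance 1e-8, at most 50 iterations) and
#' reports the Wald test of `beta` against the standard normal. Samples
#' with missing dosage are dropped. A constant dosage yields a flagged
#' result with `p = NA`; non-convergence or `|beta| > 10` (the typical
#' signature of complete separation) is flagged as non-converged rather
#' than rescued.
#'
#' @param y binary response (0/1, logical, or a factor whose second level
#'   is the event).
#' @param dosage numeric alt-allele dosage vector (`NA` allowed).
#' @param covariates optional numeric matrix of covariates (no intercept
#'   column; one row per sample).
#' @param tol IRLS convergence tolerance.
#' @param max_iter IRLS iteration cap.
#' @return list: `beta`, `se`, `p`, `converged`, `flag`
#'   (`"ok"`, `"constant_dosage"`, `"non_converged"`), `n`.
#' @export
fit_logistic <- function(y, dosage, covariates = NULL,
                         tol = 1e-8, max_iter = 50L) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  ok <- !is.na(dosage) & !is.na(y)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    ok <- ok & stats::complete.cases(covariates)
  }
  y <- y[ok]
  d <- dosage[ok]
  n <- length(y)
  flagged <- function(flag) list(beta = NA_real_, se = NA_real_, p = NA_real_,
                                 converged = FALSE, flag = flag, n = n)
  if (n == 0 || stats::var(d) == 0) return(flagged("constant_dosage"))
  x <- cbind(`(Intercept)` = 1, dosage = d,
             if (!is.null(covariates)) covariates[ok, , drop = FALSE])
  if (n < ncol(x) + 1L) stop("need at least one more sample than parameters")

  fit <- suppressWarnings(
    stats::glm.fit(x, y, family = stats::binomial(),
                   control = list(epsilon = tol, maxit = max_iter))
  )
  co <- fit$coefficients
  beta <- unname(co["dosage"])
  # covariance of the coefficients from the final weighted least squares
  r_mat <- qr.R(fit$qr)
  piv <- fit$qr$pivot
  cov_un <- chol2inv(r_mat)
  se_all <- rep(NA_real_, ncol(x))
  se_all[piv[seq_len(ncol(r_mat))]] <- sqrt(diag(cov_un))
  se <- se_all[2L]
  conv <- isTRUE(fit$converged) && is.finite(beta) && is.finite(se) &&
    abs(beta) <= 10
  p <- if (is.finite(beta) && is.finite(se) && se > 0) {
    2 * stats::pnorm(-abs(beta / se))
  } else NA_real_
  list(beta = beta, se = se, p = p, converged = conv,
       flag = if (conv) "ok" else "non_converged", n = n)
}

# covariate matrix for a model over a sample subset; constant columns
# (e.g. center within a single-center stratum) are dropped
build_covariates <- function(samples, model, pcs = NULL) {
  mats <- list()
  if ("center" %in% model$covariates) {
    cf <- factor(samples$center, levels = CENTER_LEVELS)
    mm <- stats::model.matrix(~cf)[, -1, drop = FALSE]
    colnames(mm) <- paste0("center", levels(cf)[-1])
    mats$center <- mm
  }
  if ("pcs" %in% model$covariates && !is.null(pcs) && ncol(pcs) > 0) {
    colnames(pcs) <- paste0("PC", seq_len(ncol(pcs)))
    mats$pcs <- pcs
  }
  if ("sex" %in% model$covariates) {
    mats$sex <- cbind(sexM = as.numeric(samples$sex == "M"))
  }
  if ("apoe_cov" %in% model$covariates && "apoe_cov" %in% names(samples)) {
    mats$apoe <- cbind(apoe_cov = as.numeric(samples$apoe_cov))
  }
  if ("age" %in% model$covariates && "age" %in% names(samples)) {
    mats$age <- cbind(age = as.numeric(samples$age))
  }
  x <- do.call(cbind, mats)
  if (is.null(x)) return(NULL)
  keep <- apply(x, 2, function(col) stats::var(col, na.rm = TRUE) > 0)
  x <- x[, keep, drop = FALSE]
  if (ncol(x) == 0) NULL else x
}

# resolve a stratum name to a logical sample mask
stratum_mask <- function(samples, stratum) {
  switch(stratum,
    full = rep(TRUE, nrow(samples)),
    C1 = , C2 = , C3 = samples$center == stratum,
    KitA = , KitB = samples$kit == stratum,
    stop("unknown stratum: ", stratum)
  )
}

#' Per-variant additive logistic association
#'
#' Runs [fit_logistic()] for every variant over the requested stratum
#' (`"full"`, one center, or one capture kit). Case and control minor
#' allele frequencies are computed from the called genotypes within the
#' stratum. Within a single-center or single-kit stratum the center
#' covariate becomes constant and is dropped from the design.
#'
#' @param calls a [call_set()] (already variant-filtered).
#' @param samples sample records aligned with `calls$samples`.
#' @param model a [model_spec()].
#' @param stratum `"full"`, `"C1"`, `"C2"`, `"C3"`, `"KitA"` or `"KitB"`.
#' @param pcs PC score matrix used as covariates: either one row per
#'   sample of `calls` (subset to the stratum internally) or one row per
#'   stratum sample. `NULL` for none.
#' @param variants optional variant indices to test (default: all).
#' @return data.frame of class `assoc_result`: `variant_id`, `stratum`,
#'   `model`, `beta`, `se`, `p`, `maf_case`, `maf_ctrl`, `converged`,
#'   `flag`, `n`.
#' @export
run_association <- function(calls, samples, model = model_spec("M1"),
                            stratum = "full", pcs = NULL, variants = NULL) {
  stopifnot(inherits(calls, "call_set"), inherits(model, "model_spec"))
  if (!identical(calls$samples, samples$sample_id)) {
    stop("calls and samples are not aligned")
  }
  mask <- stratum_mask(samples, stratum)
  s_sub <- samples[mask, , drop = FALSE]
  if (length(unique(s_sub$phenotype)) < 2) {
    stop("stratum ", stratum, " has fewer than 2 phenotype classes")
  }
  if (!is.null(pcs)) {
    pcs <- as.matrix(pcs)
    if (nrow(pcs) == nrow(samples)) {
      pcs <- pcs[mask, , drop = FALSE]
    } else if (nrow(pcs) != sum(mask)) {
      stop("pcs rows match neither the cohort nor the stratum")
    }
  }
  vi <- variants %||% seq_len(n_variants(calls))
  y <- as.numeric(s_sub$phenotype == "case")
  covar <- build_covariates(s_sub, model, pcs)
  gt <- calls$gt[vi, mask, drop = FALSE]

  case <- s_sub$phenotype == "case"
  maf_case <- fold_maf(called_aaf(calls, which(mask)[case], vi))
  maf_ctrl <- fold_maf(called_aaf(calls, which(mask)[!case], vi))

  res <- vector("list", length(vi))
  for (i in seq_along(vi)) {
    res[[i]] <- fit_logistic(y, gt[i, ], covar)
  }
  out <- data.frame(
    variant_id = variant_key(calls)[vi],
    stratum = stratum,
    model = model$id,
    beta = vapply(res, `[[`, 0, "beta"),
    se = vapply(res, `[[`, 0, "se"),
    p = vapply(res, `[[`, 0, "p"),
    maf_case = maf_case,
    maf_ctrl = maf_ctrl,
    converged = vapply(res, `[[`, TRUE, "converged"),
    flag = vapply(res, `[[`, "", "flag"),
    n = vapply(res, `[[`, 0L, "n"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Bonferroni-corrected significance threshold
#'
#' @param n_tests number of tests performed (>= 1).
#' @param alpha family-wise error rate (default 0.05).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  alpha / n_tests
}

#' Flag batch-exclusive association signals
#'
#' A variant significant in the full cohort is *exclusive* to a kit when
#' it reaches the per-stratum threshold in that kit's stratum while
#' showing no evidence at all (p above the null floor) in the other
#' kit's stratum; otherwise it is *concordant*. Variants below full-cohort
#' significance are `not_significant`. A stratum fit flagged
#' `constant_dosage` (the signature of complete allele dropout) counts as
#' "no evidence" (p treated as 1); a variant genuinely absent from a
#' stratum table is flagged `indeterminate` with a message.
#'
#' @param results_full full-cohort [run_association()] table.
#' @param results_kitA,results_kitB per-kit stratum tables.
#' @param threshold full-cohort significance threshold
#'   (see [bonferroni_threshold()]).
#' @param stratum_threshold per-stratum significance threshold (default:
#'   same as `threshold`).
#' @param null_floor p-value above which a stratum is deemed to show no
#'   evidence (default 0.05).
#' @return data.frame: `variant_id`, `p_full`, `p_kitA`, `p_kitB`, `flag`
#'   in `{concordant, exclusive_KitA, exclusive_KitB, not_significant,
#'   indeterminate}`.
#' @export
flag_batch_exclusive <- function(results_full, results_kitA, results_kitB,
                                 threshold, stratum_threshold = threshold,
                                 null_floor = 0.05) {
  ids <- results_full$variant_id
  effective_p <- function(tab) {
    idx <- match(ids, tab$variant_id)
    p <- tab$p[idx]
    missing_row <- is.na(idx)
    dropout <- !missing_row & tab$flag[replace(idx, missing_row, 1L)] == "constant_dosage"
    p[dropout] <- 1
    list(p = p, missing = missing_row)
  }
  pa <- effective_p(results_kitA)
  pb <- effective_p(results_kitB)
  n_missing <- sum(pa$missing | pb$missing)
  if (n_missing > 0) {
    message(n_missing, " variant(s) missing a stratum result; flagged indeterminate")
  }
  p_full <- results_full$p
  flag <- rep("not_significant", length(ids))
  sig <- !is.na(p_full) & p_full < threshold
  a_sig <- !is.na(pa$p) & pa$p < stratum_threshold
  b_sig <- !is.na(pb$p) & pb$p < stratum_threshold
  a_null <- !is.na(pa$p) & pa$p > null_floor
  b_null <- !is.na(pb$p) & pb$p > null_floor
  flag[sig] <- "concordant"
  flag[sig & a_sig & b_null] <- "exclusive_KitA"
  flag[sig & b_sig & a_null] <- "exclusive_KitB"
  flag[pa$missing | pb$missing] <- "indeterminate"
  data.frame(variant_id = ids, p_full = p_full, p_kitA = pa$p, p_kitB = pb$p,
             flag = flag, stringsAsFactors = FALSE)
}
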