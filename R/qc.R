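#' Quality-control thresholds
#'
#' Container for every threshold the QC stages apply. Defaults are the
#' published values of the motivating study: per-sample SNP call rate
#' > 95%, depth >= 10x at >= 90% of called variants, transition/transversion
#' ratio > 2.75; association-variant filters VQSLOD > 0, control-sample HWE
#' exact p >= 1e-6 and >= 10 alternative-supporting reads across the
#' cohort; and the ancestry-pruning rules MAF >= 5%, HWE p >= 1e-4,
#' pairwise r^2 <= 0.2 within 0.1 Mb windows, plus an optional excluded
#' regions table (BED-style, 0-based half-open; empty by default for
#' synthetic genomes).
#'
#' @param call_rate_floor per-sample SNP call-rate floor.
#' @param depth_min per-call depth defining "well covered".
#' @param depth_frac required fraction of called variants at
#'   `depth_min` or more.
#' @param titv_floor per-sample transition/transversion floor.
#' @param hwe_assoc_p association-filter HWE floor (control samples).
#' @param alt_read_floor minimum alternative-supporting reads across the
#'   cohort.
#' @param vqslod_floor site-score floor (retain strictly above).
#' @param prune_maf pruning MAF floor.
#' @param prune_hwe_p pruning HWE floor.
#' @param ld_r2 pruning r-squared ceiling.
#' @param ld_window_bp pruning window in base pairs.
#' @param excluded_regions data.frame `chrom`, `start`, `end` (0-based
#'   half-open) or `NULL`.
#' @return object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(call_rate_floor = 0.95,
                          depth_min = 10L,
                          depth_frac = 0.90,
                          titv_floor = 2.75,
                          hwe_assoc_p = 1e-6,
                          alt_read_floor = 10L,
                          vqslod_floor = 0,
                          prune_maf = 0.05,
                          prune_hwe_p = 1e-4,
                          ld_r2 = 0.2,
                          ld_window_bp = 1e5,
                          excluded_regions = NULL) {
  vals <- list(call_rate_floor = call_rate_floor, depth_min = depth_min,
               depth_frac = depth_frac, titv_floor = titv_floor,
               hwe_assoc_p = hwe_assoc_p, alt_read_floor = alt_read_floor,
               vqslod_floor = vqslod_floor, prune_maf = prune_maf,
               prune_hwe_p = prune_hwe_p, ld_r2 = ld_r2,
               ld_window_bp = ld_window_bp)
  if (!all(vapply(vals, function(v) is.numeric(v) && is.finite(v), TRUE))) {
    stop("all thresholds must be finite numbers")
  }
  if (!is.null(excluded_regions)) {
    stopifnot(is.data.frame(excluded_regions),
              all(c("chrom", "start", "end") %in% names(excluded_regions)))
  }
  structure(c(vals, list(excluded_regions = excluded_regions)),
            class = "qc_thresholds")
}

# transition = A<->G or C<->T
is_transition <- function(ref, alt) {
  (ref %in% c("A", "G") & alt %in% c("A", "G")) |
    (ref %in% c("C", "T") & alt %in% c("C", "T"))
}

#' Sample-level quality control
#'
#' A sample fails if its SNP call rate is at or below the floor, if fewer
#' than the required fraction of its called variants reach the depth
#' minimum, or if its transition/transversion ratio among carried
#' alternative alleles is at or below the floor. All reasons are
#' enumerated.
#'
#' @param calls a [call_set()].
#' @param thresholds a [qc_thresholds()].
#' @return data.frame: `sample_id`, `call_rate`, `depth_frac`, `titv`,
#'   `pass`, `reasons` (comma-separated; empty when passing).
#' @export
sample_qc <- function(calls, thresholds = qc_thresholds()) {
  stopifnot(inherits(calls, "call_set"), n_variants(calls) >= 1)
  called <- !is.na(calls$gt)
  call_rate <- colMeans(called)
  deep <- called & (calls$dp >= thresholds$depth_min)
  depth_frac <- colSums(deep) / pmax(colSums(called), 1L)
  ti <- is_transition(calls$variants$ref, calls$variants$alt)
  carries <- !is.na(calls$gt) & calls$gt >= 1L
  n_ti <- colSums(carries & ti)
  n_tv <- colSums(carries & !ti)
  titv <- ifelse(n_tv > 0, n_ti / n_tv, Inf)

  reasons <- mapply(function(cr, dfr, tt) {
    r <- character(0)
    if (cr <= thresholds$call_rate_floor) r <- c(r, "call_rate")
    if (dfr < thresholds$depth_frac) r <- c(r, "depth")
    if (tt <= thresholds$titv_floor) r <- c(r, "titv")
    paste(r, collapse = ",")
  }, call_rate, depth_frac, titv)

  data.frame(
    sample_id = calls$samples,
    call_rate = call_rate,
    depth_frac = depth_frac,
    titv = titv,
    pass = reasons == "",
    reasons = unname(reasons),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

# core exact HWE p for one table: observed het count, minor allele count,
# number of diploid individuals. Conditional distribution of heterozygote
# counts given allele counts; two-sided "probability <= observed" rule.
hwe_exact_one <- function(het, rare, n) {
  if (rare == 0L || n == 0L) return(1)
  hs <- seq.int(rare %% 2L, rare, by = 2L)
  # log P(h) = log[ n! 2^h rare! (2n-rare)! / ( ((rare-h)/2)! h! (n-(rare+h)/2)! (2n)! ) ]
  lp <- lgamma(n + 1) + hs * log(2) - lgamma((rare - hs) / 2 + 1) -
    lgamma(hs + 1) - lgamma(n - (rare + hs) / 2 + 1)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(het, hs)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-10)]))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test on genotype counts: given the allele counts, the
#' p-value is the total probability of heterozygote counts whose exact
#' conditional probability does not exceed that of the observed count
#' (two-sided "probability <= observed" summation, not mid-p). Monomorphic
#' sites return 1.
#'
#' @param n_AA,n_Aa,n_aa nonnegative genotype counts (vectors recycle).
#' @return numeric vector of exact p-values in (0, 1\].
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  k <- max(length(n_AA), length(n_Aa), length(n_aa))
  n_AA <- rep_len(as.integer(n_AA), k)
  n_Aa <- rep_len(as.integer(n_Aa), k)
  n_aa <- rep_len(as.integer(n_aa), k)
  if (any(n_AA < 0 | n_Aa < 0 | n_aa < 0)) stop("genotype counts must be >= 0")
  if (any(n_AA + n_Aa + n_aa == 0L)) stop("total genotype count must be > 0")
  n <- n_AA + n_Aa + n_aa
  rare <- pmin(2L * n_AA + n_Aa, 2L * n_aa + n_Aa)
  vapply(seq_len(k), function(i) hwe_exact_one(n_Aa[i], rare[i], n[i]),
         numeric(1))
}

#' Variant-level filters for association analysis
#'
#' Retains a variant iff its VQSLOD-style score is strictly above the
#' floor, its exact HWE p-value in the control samples is at or above the
#' floor, and its alternative allele is supported by at least the required
#' number of reads across the whole cohort. (Only biallelic SNPs are
#' representable, so that criterion holds by construction.) The filters
#' are independent predicates, so their order is irrelevant.
#'
#' @param calls a [call_set()].
#' @param controls logical mask, integer index or sample ids of the
#'   control samples (nonempty).
#' @param thresholds a [qc_thresholds()].
#' @return list: `retained` (integer variant indices), `hwe_p` (control HWE
#'   p per variant), `counts` (named exclusion counts per filter; variants
#'   may count toward several), `n_excluded`.
#' @export
variant_filters <- function(calls, controls, thresholds = qc_thresholds()) {
  stopifnot(inherits(calls, "call_set"))
  if (is.character(controls)) controls <- match(controls, calls$samples)
  if (is.logical(controls)) controls <- which(controls)
  if (length(controls) == 0) stop("control subset must be nonempty")

  cnt <- genotype_counts(calls, controls)
  hwe_p <- hwe_exact_p(cnt[, "n_AA"], cnt[, "n_Aa"], cnt[, "n_aa"])
  fail_vqsr <- !(calls$variants$vqslod > thresholds$vqslod_floor)
  fail_hwe <- hwe_p < thresholds$hwe_assoc_p
  alt_reads <- rowSums(calls$ad_alt)
  fail_alt <- alt_reads < thresholds$alt_read_floor

  keep <- !(fail_vqsr | fail_hwe | fail_alt)
  list(
    retained = which(keep),
    hwe_p = hwe_p,
    counts = c(vqsr = sum(fail_vqsr), hwe = sum(fail_hwe),
               alt_support = sum(fail_alt)),
    n_excluded = sum(!keep)
  )
}

# is a position inside any 0-based half-open excluded region?
in_excluded_region <- function(chrom, pos, regions) {
  if (is.null(regions) || nrow(regions) == 0) return(rep(FALSE, length(pos)))
  out <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(regions))) {
    out <- out | (chrom == regions$chrom[i] &
                    pos > regions$start[i] & pos <= regions$end[i])
  }
  out
}

#' Build the pruned high-quality variant set for PCA
#'
#' From a candidate set (typically the variants retained by
#' [variant_filters()]), drops variants with called MAF below the floor,
#' HWE exact p below the pruning floor, or lying inside an excluded
#' region; then scans left to right within each chromosome and, for every
#' pair closer than the window with genotype-dosage r-squared above the
#' ceiling, drops the later variant (the left-most variant of a correlated
#' run is kept, deterministically).
#'
#' @param calls a [call_set()].
#' @param thresholds a [qc_thresholds()].
#' @param candidates integer variant indices to start from (default: all).
#' @return integer vector of pruned variant indices (sorted).
#' @export
build_pruned_set <- function(calls, thresholds = qc_thresholds(),
                             candidates = NULL) {
  stopifnot(inherits(calls, "call_set"))
  idx <- candidates %||% seq_len(n_variants(calls))
  cnt <- genotype_counts(calls, variants = idx)
  maf <- fold_maf(called_aaf(calls, variants = idx))
  hwe_p <- hwe_exact_p(cnt[, "n_AA"], cnt[, "n_Aa"], cnt[, "n_aa"])
  excl <- in_excluded_region(calls$variants$chrom[idx],
                             calls$variants$pos[idx],
                             thresholds$excluded_regions)
  idx <- idx[!is.na(maf) & maf >= thresholds$prune_maf &
               hwe_p >= thresholds$prune_hwe_p & !excl]
  if (length(idx) < 2) return(sort(idx))

  # standardized (mean-imputed) dosage rows for fast pairwise r^2
  g <- calls$gt[idx, , drop = FALSE]
  g <- impute_row_means(g)
  mu <- rowMeans(g)
  sdv <- sqrt(pmax(rowSums((g - mu)^2), 0))
  z <- (g - mu) / ifelse(sdv > 0, sdv, 1)

  ord <- order(calls$variants$chrom[idx], calls$variants$pos[idx])
  chrom <- calls$variants$chrom[idx][ord]
  pos <- calls$variants$pos[idx][ord]
  keep <- logical(length(ord))
  kept_rows <- integer(0)
  for (i in seq_along(ord)) {
    win <- kept_rows[chrom[kept_rows] == chrom[i] &
                       pos[i] - pos[kept_rows] <= thresholds$ld_window_bp]
    ok <- TRUE
    for (j in rev(win)) {
      r <- sum(z[ord[i], ] * z[ord[j], ])
      if (r * r > thresholds$ld_r2) {
        ok <- FALSE
        break
      }
    }
    if (ok) {
      keep[i] <- TRUE
      kept_rows <- c(kept_rows, i)
    }
  }
  sort(idx[ord[keep]])
}

# mean-impute missing entries of an integer dosage matrix, row-wise
impute_row_means <- function(g) {
  g <- matrix(as.numeric(g), nrow(g), ncol(g))
  nas <- which(is.na(g), arr.ind = TRUE)
  if (nrow(nas) > 0) {
    mu <- rowMeans(g, na.rm = TRUE)
    mu[!is.finite(mu)] <- 0
    g[nas] <- mu[nas[, 1]]
  }
  g
}
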