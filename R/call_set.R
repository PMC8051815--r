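#' Multi-sample biallelic SNP call set
#'
#' Matrix-backed container for the supported VCF subset: one row per
#' biallelic SNP site, one column per sample, with called genotype dosage
#' (`0`, `1`, `2`, `NA` = missing), per-allele read depths, total depth and
#' genotype quality, plus a site-level VQSLOD-style score.
#'
#' Invariants enforced: `ad_ref + ad_alt == dp` (equal by construction in
#' the simulator, and required of parsed input), GQ present iff the
#' genotype is called.
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `vqslod`.
#' @param samples character vector of sample ids (column order).
#' @param gt integer matrix of called alt-allele dosage, `NA` for missing.
#' @param ad_ref,ad_alt integer matrices of reference/alternative read
#'   depths.
#' @param dp integer matrix of total depth.
#' @param gq integer matrix of genotype quality (0-99), `NA` where the
#'   genotype is missing.
#' @return object of class `call_set`.
#' @export
call_set <- function(variants, samples, gt, ad_ref, ad_alt, dp, gq) {
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos", "ref", "alt", "vqslod") %in% names(variants)))
  m <- nrow(variants)
  n <- length(samples)
  for (mat in list(gt, ad_ref, ad_alt, dp, gq)) {
    if (!is.matrix(mat) || nrow(mat) != m || ncol(mat) != n) {
      stop("matrix dimensions must be n_variants x n_samples")
    }
  }
  if (any(gt[!is.na(gt)] < 0L | gt[!is.na(gt)] > 2L)) {
    stop("called genotypes must be dosages 0, 1 or 2")
  }
  if (any(ad_ref + ad_alt != dp, na.rm = TRUE)) {
    stop("ad_ref + ad_alt must equal dp")
  }
  if (any(is.na(gt) != is.na(gq))) {
    stop("GQ must be present exactly where the genotype is called")
  }
  bad_snp <- nchar(variants$ref) != 1L | nchar(variants$alt) != 1L |
    variants$ref == variants$alt
  if (any(bad_snp)) stop("only biallelic SNP sites are representable")
  structure(list(
    variants = variants, samples = as.character(samples),
    gt = gt, ad_ref = ad_ref, ad_alt = ad_alt, dp = dp, gq = gq
  ), class = "call_set")
}

#' @export
print.call_set <- function(x, ...) {
  cat("call_set:", nrow(x$variants), "variants x", length(x$samples),
      "samples;", sprintf("%.2f%%", 100 * mean(is.na(x$gt))),
      "missing calls\n")
  invisible(x)
}

#' Number of variants / samples in a call set
#' @param x a `call_set`.
#' @return integer count.
#' @export
n_variants <- function(x) nrow(x$variants)

#' @rdname n_variants
#' @export
n_samples <- function(x) length(x$samples)

#' Canonical variant keys (`chrom:pos:ref:alt`)
#' @param x a `call_set` or a variant data.frame.
#' @return character vector of keys.
#' @export
variant_key <- function(x) {
  v <- if (inherits(x, "call_set")) x$variants else x
  paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
}

#' Subset a call set by variants and/or samples
#'
#' @param x a `call_set`.
#' @param variants integer or logical index over variants (rows).
#' @param samples integer or logical index over samples, or sample ids.
#' @return a `call_set`.
#' @export
subset_call_set <- function(x, variants = NULL, samples = NULL) {
  stopifnot(inherits(x, "call_set"))
  vi <- variants %||% seq_len(n_variants(x))
  si <- samples %||% seq_along(x$samples)
  if (is.character(si)) {
    si <- match(si, x$samples)
    if (anyNA(si)) stop("unknown sample id(s) in subset")
  }
  call_set(
    x$variants[vi, , drop = FALSE],
    x$samples[si],
    x$gt[vi, si, drop = FALSE],
    x$ad_ref[vi, si, drop = FALSE],
    x$ad_alt[vi, si, drop = FALSE],
    x$dp[vi, si, drop = FALSE],
    x$gq[vi, si, drop = FALSE]
  )
}

# per-variant genotype counts (hom-ref, het, hom-alt) over optional
# variant/sample subsets, without copying the container
genotype_counts <- function(x, samples = NULL, variants = NULL) {
  g <- x$gt
  if (!is.null(variants)) g <- g[variants, , drop = FALSE]
  if (!is.null(samples)) g <- g[, samples, drop = FALSE]
  cbind(
    n_AA = rowSums(g == 0L, na.rm = TRUE),
    n_Aa = rowSums(g == 1L, na.rm = TRUE),
    n_aa = rowSums(g == 2L, na.rm = TRUE)
  )
}

# per-variant alt-allele frequency from called genotypes (unfolded)
called_aaf <- function(x, samples = NULL, variants = NULL) {
  cnt <- genotype_counts(x, samples, variants)
  tot <- rowSums(cnt)
  ifelse(tot > 0, (cnt[, "n_Aa"] + 2 * cnt[, "n_aa"]) / (2 * tot), NA_real_)
}
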