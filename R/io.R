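#' Write a call set to VCF 4.2
#'
#' Emits the supported subset: biallelic SNPs with per-sample FORMAT
#' `GT:AD:DP:GQ` and a site-level `VQSLOD` INFO float. Genotypes are
#' unphased; missing calls are written `./.` with GQ `.` (read depths are
#' still emitted, as callers do).
#'
#' @param x a [call_set()].
#' @param path output file path (plain text `.vcf`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  stopifnot(inherits(x, "call_set"))
  v <- x$variants
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=varbatch",
    sprintf("##contig=<ID=%s>", unique(v$chrom)),
    "##INFO=<ID=VQSLOD,Number=1,Type=Float,Description=\"Recalibrated variant quality log-odds\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$samples), collapse = "\t")
  )
  lines <- header
  if (nrow(v) > 0) {
    gt_str <- matrix(c("0/0", "0/1", "1/1")[x$gt + 1L],
                     nrow(v), length(x$samples))
    gt_str[is.na(x$gt)] <- "./."
    gq_str <- matrix(as.character(x$gq), nrow(v), length(x$samples))
    gq_str[is.na(x$gq)] <- "."
    cells <- matrix(
      paste0(gt_str, ":", x$ad_ref, ",", x$ad_alt, ":", x$dp, ":", gq_str),
      nrow(v), length(x$samples)
    )
    fixed <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS",
                   sprintf("VQSLOD=%g", v$vqslod), "GT:AD:DP:GQ", sep = "\t")
    body <- do.call(paste,
                    c(list(fixed), as.data.frame(cells, stringsAsFactors = FALSE),
                      sep = "\t"))
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a VCF into a call set
#'
#' Parsing is delegated to `vcfR`; only biallelic SNP records are
#' representable, and any other records are rejected with a message giving
#' the count. Genotypes of `./.` (or with missing AD) are mapped to missing
#' calls. Order of records and samples is preserved.
#'
#' @param path VCF file (gzip-transparent via vcfR).
#' @return a [call_set()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  m_all <- nrow(fix)
  if (m_all == 0) {
    return(call_set(
      data.frame(chrom = character(), pos = integer(), ref = character(),
                 alt = character(), vqslod = numeric()),
      character(0),
      matrix(NA_integer_, 0, 0), matrix(0L, 0, 0), matrix(0L, 0, 0),
      matrix(0L, 0, 0), matrix(NA_integer_, 0, 0)
    ))
  }
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (any(!keep)) {
    message(sum(!keep), " non-biallelic-SNP record(s) rejected at parse")
  }
  if (!any(keep)) stop("no biallelic SNP records in ", path)
  vcf <- vcf[keep, ]
  fix <- fix[keep, , drop = FALSE]
  m <- nrow(fix)

  vqslod <- suppressWarnings(
    as.numeric(vcfR::extract.info(vcf, "VQSLOD"))
  )
  if (anyNA(vqslod)) stop("missing or malformed VQSLOD INFO field")

  gt_raw <- vcfR::extract.gt(vcf, "GT")
  samples <- colnames(gt_raw)
  n <- length(samples)
  dosage_map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
                  "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L)
  gt <- matrix(dosage_map[as.vector(gt_raw)], m, n)

  ad_raw <- vcfR::extract.gt(vcf, "AD")
  ad_parts <- data.table::tstrsplit(as.vector(ad_raw), ",", fixed = TRUE)
  ad_ref <- matrix(suppressWarnings(as.integer(ad_parts[[1]])), m, n)
  ad_alt <- matrix(suppressWarnings(as.integer(ad_parts[[2]])), m, n)
  dp <- matrix(suppressWarnings(
    as.integer(vcfR::extract.gt(vcf, "DP"))), m, n)
  gq <- matrix(suppressWarnings(
    as.integer(vcfR::extract.gt(vcf, "GQ"))), m, n)

  # AD of "." (or absent) means the call is missing
  ad_missing <- is.na(ad_ref) | is.na(ad_alt)
  gt[ad_missing] <- NA_integer_
  ad_ref[ad_missing] <- 0L
  ad_alt[ad_missing] <- 0L
  dp[ad_missing] <- 0L
  dp[is.na(dp)] <- 0L
  gq[is.na(gt)] <- NA_integer_

  variants <- data.frame(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = ref[keep], alt = alt[keep],
    vqslod = vqslod,
    stringsAsFactors = FALSE
  )
  call_set(variants, samples, gt, ad_ref, ad_alt, dp, gq)
}

.read_tsv <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else path
  utils::read.table(con, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read / write sample metadata
#'
#' Tab-separated with header
#' `sample_id  center  kit  sex  phenotype  apoe_cov` (extra columns such as
#' a truth `subpop` label are carried through). Validates center labels,
#' the center-to-kit map, and phenotype coding.
#'
#' @param path TSV file (gzip-transparent on read).
#' @return data.frame of sample records.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- .read_tsv(path)
  req <- c("sample_id", "center", "kit", "sex", "phenotype")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  bad <- setdiff(unique(df$center), CENTER_LEVELS)
  if (length(bad) > 0) stop("unknown center label(s): ", paste(bad, collapse = ", "))
  if (!all(df$kit == center_to_kit(df$center))) {
    stop("kit column inconsistent with the center-to-kit design map")
  }
  bad_ph <- setdiff(unique(df$phenotype), c("case", "control"))
  if (length(bad_ph) > 0) {
    stop("phenotype must be 'case' or 'control'; found: ",
         paste(bad_ph, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in metadata")
  df
}

#' @rdname read_metadata
#' @param samples data.frame of sample records.
#' @export
write_metadata <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a reference minor-allele-frequency table
#'
#' Two tab-separated columns: `variant_id` (`chrom:pos:ref:alt`) and `maf`.
#' Frequencies are folded to the minor allele on read.
#'
#' @param path TSV file.
#' @return named numeric vector of reference MAFs keyed by variant id.
#' @export
read_ref_maf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- .read_tsv(path)
  if (!all(c("variant_id", "maf") %in% names(df))) {
    stop("reference MAF table must have columns variant_id, maf")
  }
  maf <- fold_maf(as.numeric(df$maf))
  if (any(!is.finite(maf) | maf < 0)) stop("malformed reference MAF values")
  stats::setNames(maf, df$variant_id)
}

#' @rdname read_ref_maf
#' @param ref named numeric vector of MAFs.
#' @export
write_ref_maf <- function(ref, path) {
  utils::write.table(
    data.frame(variant_id = names(ref), maf = unname(ref)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Check that VCF samples and metadata agree
#'
#' @param calls a [call_set()].
#' @param samples metadata data.frame.
#' @return invisibly `TRUE`; hard error listing offending ids otherwise.
#' @export
check_sample_match <- function(calls, samples) {
  only_vcf <- setdiff(calls$samples, samples$sample_id)
  only_meta <- setdiff(samples$sample_id, calls$samples)
  if (length(only_vcf) > 0 || length(only_meta) > 0) {
    stop("sample sets disagree; VCF-only: [",
         paste(only_vcf, collapse = ", "), "]; metadata-only: [",
         paste(only_meta, collapse = ", "), "]")
  }
  invisible(TRUE)
}

#' Write a simulated dataset to disk
#'
#' Emits `cohort.vcf` (VCF 4.2, FORMAT `GT:AD:DP:GQ`, INFO `VQSLOD`),
#' `metadata.tsv`, `truth.json` and, when truth is supplied, a synthetic
#' reference MAF table `ref_maf.tsv` holding the true population
#' frequencies (subpopulation average, folded) as the stand-in for an
#' external reference panel.
#'
#' @param calls a [call_set()].
#' @param samples sample records.
#' @param truth optional `truth_table`.
#' @param outdir output directory, created if needed.
#' @return named character vector of the files written.
#' @export
emit_dataset <- function(calls, samples, truth = NULL, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- c(vcf = file.path(outdir, "cohort.vcf"),
             metadata = file.path(outdir, "metadata.tsv"))
  write_vcf(calls, files[["vcf"]])
  write_metadata(samples, files[["metadata"]])
  if (!is.null(truth)) {
    files[["truth"]] <- file.path(outdir, "truth.json")
    write_truth(truth, files[["truth"]])
    files[["ref_maf"]] <- file.path(outdir, "ref_maf.tsv")
    pooled <- rowMeans(truth$subpop_freq)
    write_ref_maf(stats::setNames(fold_maf(pooled), variant_key(truth$variants)),
                  files[["ref_maf"]])
  }
  files
}

#' @rdname emit_dataset
#' @param dir directory written by `emit_dataset`.
#' @return `read_dataset`: list with `calls`, `samples` and, if present,
#'   `truth` and `ref_maf`.
#' @export
read_dataset <- function(dir) {
  calls <- read_vcf(file.path(dir, "cohort.vcf"))
  samples <- read_metadata(file.path(dir, "metadata.tsv"))
  check_sample_match(calls, samples)
  out <- list(calls = calls, samples = samples)
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) out$truth <- read_truth(tj)
  rm <- file.path(dir, "ref_maf.tsv")
  if (file.exists(rm)) out$ref_maf <- read_ref_maf(rm)
  out
}

#' Serialize / deserialize simulation ground truth as JSON
#' @param truth a `truth_table`.
#' @param path JSON file path.
#' @export
write_truth <- function(truth, path) {
  obj <- list(
    genotypes = truth$genotypes,
    variants = truth$variants,
    subpop_freq = truth$subpop_freq,
    subpop = truth$subpop,
    alpha = truth$alpha,
    major_locus = truth$major_locus
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    genotypes = matrix(as.integer(obj$genotypes), nrow = nrow(obj$genotypes)),
    variants = as.data.frame(obj$variants, stringsAsFactors = FALSE),
    subpop_freq = as.matrix(obj$subpop_freq),
    subpop = as.integer(obj$subpop),
    alpha = as.numeric(obj$alpha),
    major_locus = if (is.null(obj$major_locus)) NA_integer_ else as.integer(obj$major_locus)
  ), class = "truth_table")
}
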