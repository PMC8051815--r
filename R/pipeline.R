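#' Run the full batch-effect analysis pipeline
#'
#' Orchestrates simulate (or supplied data) -> sample QC -> variant
#' filters -> pruned-set PCA -> stratified association -> batch-exclusive
#' flagging -> variant-level batch diagnostics, from one configuration.
#' Every threshold actually applied is recorded in the manifest, and a
#' rerun with the same configuration is byte-identical.
#'
#' @param config a [sim_config()] (ignored when `data` is supplied, except
#'   for its seed).
#' @param data optional list with `calls`, `samples` and optionally
#'   `truth`, `ref_maf`, to analyse pre-existing data instead of
#'   simulating.
#' @param outdir optional output directory; when given, association
#'   tables, metrics, flags, diagnostics JSON and a run manifest are
#'   written eagerly.
#' @param models character vector of [model_spec()] ids to fit.
#' @param strata strata to fit (always includes `full`, `KitA`, `KitB`,
#'   which the flagging step needs).
#' @param thresholds a [qc_thresholds()].
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @param null_floor no-evidence floor for [flag_batch_exclusive()].
#' @param stratum_threshold per-stratum significance threshold (default:
#'   the full-cohort Bonferroni threshold).
#' @param tail_frac tail mass per side for [partition_tails()].
#' @param aaf_mode AAF averaging mode (see [per_variant_batch_metrics()]).
#' @param max_pcs cap for [retain_pcs()].
#' @param recompute_stratum_pcs recompute PC scores within each stratum
#'   (default) instead of reusing the full-cohort projection.
#' @param cluster_k_range candidate subpopulation counts for
#'   [cluster_subpops()], or `NULL` to skip clustering.
#' @return a `pipeline_report` list; see Details in the package vignette.
#' @export
run_pipeline <- function(config, data = NULL, outdir = NULL,
                         models = "M1",
                         strata = c("full", "C1", "C2", "C3", "KitA", "KitB"),
                         thresholds = qc_thresholds(),
                         alpha = 0.05, null_floor = 0.05,
                         stratum_threshold = NULL,
                         tail_frac = 0.05,
                         aaf_mode = "carriers",
                         max_pcs = 10L,
                         recompute_stratum_pcs = TRUE,
                         cluster_k_range = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  strata <- union(c("full", "KitA", "KitB"), strata)

  sim <- stage("simulate", {
    if (is.null(data)) {
      out <- simulate_cohort(config)
      out$calls <- simulate_calls(out$truth, out$samples, config)
      out$ref_maf <- stats::setNames(
        fold_maf(rowMeans(out$truth$subpop_freq)),
        variant_key(out$truth$variants))
      out
    } else {
      data
    }
  })
  calls <- sim$calls
  samples <- sim$samples
  check_sample_match(calls, samples)

  sqc <- stage("sample_qc", sample_qc(calls, thresholds))
  keep_s <- which(sqc$pass)
  calls <- subset_call_set(calls, samples = keep_s)
  samples <- samples[keep_s, , drop = FALSE]

  controls <- samples$phenotype == "control"
  vf <- stage("variant_filters", variant_filters(calls, controls, thresholds))
  retained <- vf$retained
  n_tests <- length(retained)
  threshold <- if (n_tests > 0) bonferroni_threshold(n_tests, alpha) else NA_real_
  stratum_threshold <- stratum_threshold %||% threshold

  report <- list(
    config = if (is.null(data)) config else NULL,
    sample_qc = sqc,
    filter_counts = vf$counts,
    retained = retained,
    n_tests = n_tests,
    threshold = threshold,
    samples = samples,
    truth = sim$truth
  )

  if (n_tests == 0) {
    report$association <- list()
    report$flags <- data.frame()
    report$metrics <- data.frame()
    report$manifest <- pipeline_manifest(config, thresholds, alpha,
                                         null_floor, tail_frac, aaf_mode,
                                         n_tests, threshold)
    class(report) <- "pipeline_report"
    if (!is.null(outdir)) write_report(report, outdir)
    return(report)
  }

  pruned <- stage("prune", build_pruned_set(calls, thresholds, retained))
  pca <- stage("pca", suppressMessages(genotype_pca(calls, variants = pruned)))
  n_pcs <- suppressWarnings(retain_pcs(pca, max_pcs))
  pcs <- if (n_pcs > 0) pca$vectors[, seq_len(n_pcs), drop = FALSE] else NULL
  report$pruned <- pruned
  report$eigenvalues <- pca$values
  report$n_pcs <- n_pcs
  if (!is.null(cluster_k_range)) {
    report$subpop_clusters <- stage(
      "cluster", cluster_subpops(pca, cluster_k_range, seed = config$seed))
  }

  assoc <- stage("association", {
    out <- list()
    for (mid in models) {
      model <- model_spec(mid)
      for (st in strata) {
        st_pcs <- pcs
        if (st != "full" && recompute_stratum_pcs && n_pcs > 0) {
          mask <- stratum_mask(samples, st)
          st_pca <- suppressMessages(
            genotype_pca(calls, variants = pruned, samples = which(mask)))
          st_k <- suppressWarnings(retain_pcs(st_pca, max_pcs))
          st_pcs <- if (st_k > 0) {
            st_pca$vectors[, seq_len(st_k), drop = FALSE]
          } else NULL
        }
        out[[paste(mid, st, sep = ".")]] <- run_association(
          calls, samples, model, st, pcs = st_pcs, variants = retained)
      }
    }
    out
  })
  report$association <- assoc

  first <- models[1]
  report$flags <- stage("flags", flag_batch_exclusive(
    assoc[[paste(first, "full", sep = ".")]],
    assoc[[paste(first, "KitA", sep = ".")]],
    assoc[[paste(first, "KitB", sep = ".")]],
    threshold, stratum_threshold, null_floor
  ))

  diag_calls <- subset_call_set(calls, variants = retained)
  report$metrics <- stage("metrics", suppressMessages(
    per_variant_batch_metrics(diag_calls, samples, aaf_mode)))
  report$tails <- stage("tails", partition_tails(report$metrics, tail_frac))
  report$bimodality <- stage("bimodality", {
    lapply(stats::setNames(KIT_LEVELS, KIT_LEVELS), function(kit) {
      x <- log2(report$metrics[[paste0("mean_aaf_", kit)]])
      if (sum(is.finite(x)) >= 50) {
        suppressMessages(fit_aaf_bimodality(x))
      } else NULL
    })
  })
  report$separation <- stage("separation", {
    tail_idx <- retained[report$tails$any_tail]
    mid_idx <- retained[!report$tails$any_tail]
    list(
      tail = if (length(tail_idx) >= 2)
        subset_pca_separation(calls, samples, tail_idx) else NA_real_,
      middle = if (length(mid_idx) >= 2)
        subset_pca_separation(calls, samples, mid_idx) else NA_real_
    )
  })
  if (!is.null(sim$ref_maf)) {
    report$concordance <- stage("concordance", suppressMessages(
      maf_concordance(kit_control_maf(diag_calls, samples), sim$ref_maf)))
  }
  report$capture_efficiency <- stage("capture_efficiency", {
    lapply(stats::setNames(KIT_LEVELS, KIT_LEVELS), function(kit) {
      estimate_capture_efficiency(diag_calls, samples, kit)
    })
  })

  report$manifest <- pipeline_manifest(config, thresholds, alpha, null_floor,
                                       tail_frac, aaf_mode, n_tests, threshold)
  class(report) <- "pipeline_report"
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

pipeline_manifest <- function(config, thresholds, alpha, null_floor,
                              tail_frac, aaf_mode, n_tests, threshold) {
  list(
    package_version = as.character(utils::packageVersion("varbatch")),
    seed = if (!is.null(config)) config$seed else NA_integer_,
    thresholds = unclass(thresholds)[
      setdiff(names(unclass(thresholds)), "excluded_regions")],
    alpha = alpha,
    null_floor = null_floor,
    tail_frac = tail_frac,
    aaf_mode = aaf_mode,
    n_tests = n_tests,
    bonferroni_threshold = threshold
  )
}

write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  tsv(report$sample_qc, "sample_qc.tsv")
  if (length(report$association) > 0) {
    tsv(do.call(rbind, report$association), "association.tsv")
  }
  if (nrow(report$flags) > 0) tsv(report$flags, "flags.tsv")
  if (is.data.frame(report$metrics) && nrow(report$metrics) > 0) {
    tsv(report$metrics, "batch_metrics.tsv")
    tsv(report$tails, "tails.tsv")
  }
  diag <- list(
    filter_counts = as.list(report$filter_counts),
    n_tests = report$n_tests,
    threshold = report$threshold,
    n_pcs = report$n_pcs,
    eigenvalues = utils::head(report$eigenvalues, 20),
    separation = report$separation,
    flag_counts = if (nrow(report$flags) > 0) {
      as.list(table(report$flags$flag))
    } else list(),
    concordance_counts = if (!is.null(report$concordance)) {
      as.list(report$concordance$counts)
    } else NULL,
    bimodality = lapply(report$bimodality, function(b) {
      if (is.null(b)) NULL else unclass(b)
    })
  )
  jsonlite::write_json(diag, file.path(outdir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  jsonlite::write_json(report$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report:", x$n_tests, "variants tested,",
      sum(x$sample_qc$pass), "samples passing QC\n")
  invisible(x)
}

#' Summarize a pipeline report
#'
#' Counts per filter, per batch-exclusivity flag and per ratio tail, plus
#' the top variants sorted by full-cohort p-value.
#'
#' @param report a `pipeline_report` from [run_pipeline()].
#' @param n_top rows of the top-variant table.
#' @return object of class `pipeline_summary`: `n_tested`,
#'   `filter_counts`, `flag_counts`, `tail_counts`, `top` (sorted
#'   nondecreasing in p).
#' @export
summarize <- function(report, n_top = 20L) {
  stopifnot(inherits(report, "pipeline_report"))
  if (report$n_tests == 0) {
    out <- list(n_tested = 0L, filter_counts = report$filter_counts,
                flag_counts = integer(0), tail_counts = integer(0),
                top = data.frame())
    class(out) <- "pipeline_summary"
    return(out)
  }
  full <- report$association[[grep("\\.full$", names(report$association))[1]]]
  ord <- order(full$p, na.last = TRUE)
  top <- full[utils::head(ord, n_top), , drop = FALSE]
  flags <- report$flags$flag[match(top$variant_id, report$flags$variant_id)]
  top$flag <- flags
  tail_counts <- if (!is.null(report$tails)) {
    c(any_tail = sum(report$tails$any_tail),
      aaf_left = sum(report$tails$aaf_tail == "left5", na.rm = TRUE),
      aaf_right = sum(report$tails$aaf_tail == "right5", na.rm = TRUE))
  } else integer(0)
  out <- list(
    n_tested = report$n_tests,
    filter_counts = report$filter_counts,
    flag_counts = table(report$flags$flag),
    tail_counts = tail_counts,
    threshold = report$threshold,
    top = top
  )
  class(out) <- "pipeline_summary"
  out
}

#' @export
print.pipeline_summary <- function(x, ...) {
  if (x$n_tested == 0) {
    cat("0 variants tested (all excluded by filters)\n")
    cat("exclusions:", paste(names(x$filter_counts), x$filter_counts,
                             sep = "=", collapse = ", "), "\n")
    return(invisible(x))
  }
  cat(x$n_tested, "variants tested; Bonferroni threshold",
      format(x$threshold, digits = 3), "\n")
  cat("exclusions:", paste(names(x$filter_counts), x$filter_counts,
                           sep = "=", collapse = ", "), "\n")
  cat("flags:", paste(names(x$flag_counts), as.integer(x$flag_counts),
                      sep = "=", collapse = ", "), "\n")
  if (length(x$tail_counts) > 0) {
    cat("ratio tails:", paste(names(x$tail_counts), x$tail_counts,
                              sep = "=", collapse = ", "), "\n")
  }
  cat("top variants by full-cohort p:\n")
  print(utils::head(x$top[, c("variant_id", "p", "maf_case", "maf_ctrl",
                              "flag")], 10), row.names = FALSE)
  invisible(x)
}
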