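#' Run the full subtype-and-signature pipeline
#'
#' Orchestrates the analysis end to end on a cohort: per-batch
#' standardization (when batch labels are present), consensus subtyping on
#' the HOX feature genes, differential expression between the two subtypes,
#' a 2:1 train/test split, signature derivation on the training set
#' (random-forest elimination, exhaustive subset search, optimal-subset
#' selection), and survival evaluation of the selected signature on the
#' training set, the held-out test set, and an optional external cohort.
#' All randomness flows from `config$seed` via fixed per-stage offsets, so a
#' run is fully reproducible.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{cohort}{a `synthetic_cohort`, or `cohort_spec` to generate one;
#'       alternatively supply `expression` (matrix), `clinical` (data
#'       frame) and optional `batch`.}
#'     \item{k_range, n_iter, subsample_fraction}{consensus parameters
#'       (defaults 2:4, 1000, 0.8).}
#'     \item{p_threshold, lfc_threshold}{DEG screen (defaults 0.01, 1).}
#'     \item{n_trees, drop_fraction, target_n, tolerance}{signature
#'       derivation (defaults 1000, 1/3, 9, 0.01).}
#'     \item{seed}{master seed (default 1).}
#'     \item{external}{optional external cohort (same shape as `cohort`)
#'       for independent validation.}
#'     \item{out_dir}{optional directory; when given, all tables, the
#'       signature JSON and the run manifest are written there.}
#'   }
#' @return list of class `hox_pipeline`: `subtyping` (consensus result),
#'   `deg` (DEG table), `deg_genes`, `split`, `signature` (the fitted
#'   `centroid_signature`), `evaluation` (train/test/external metric
#'   lists), and `manifest` (parameters, seeds, stage summaries).
#' @export
run_hox_pipeline <- function(config) {
  cfg <- utils::modifyList(list(
    k_range = 2:4, n_iter = 1000L, subsample_fraction = 0.8,
    p_threshold = 0.01, lfc_threshold = 1,
    n_trees = 1000L, drop_fraction = 1 / 3, target_n = 9L,
    tolerance = 0.01, seed = 1L, external = NULL, out_dir = NULL
  ), config)
  seed <- .check_count(cfg$seed, "seed", min = 0L)

  ch <- .resolve_cohort(cfg)
  expr <- ch$expression
  clinical <- ch$clinical
  idx <- match(colnames(expr), clinical$sample_id)
  if (anyNA(idx)) {
    stop("clinical table does not cover all expression samples",
         call. = FALSE)
  }
  clinical <- clinical[idx, , drop = FALSE]
  if (!is.null(ch$batch) && nlevels(factor(ch$batch)) > 1L) {
    expr <- batch_standardize(expr, ch$batch)
  }

  # consensus subtyping on the HOX feature genes present in the matrix
  hox <- intersect(hox_gene_list(), rownames(expr))
  if (length(hox) < 2L) stop("pipeline aborted at stage 'subtype': fewer ",
                             "than 2 HOX feature genes in the matrix",
                             call. = FALSE)
  subtyping <- consensus_cluster(expr[hox, , drop = FALSE],
                                 k_range = cfg$k_range, n_iter = cfg$n_iter,
                                 subsample_fraction = cfg$subsample_fraction,
                                 seed = seed + 101L)
  if (subtyping$chosen_k != 2L) {
    warning("consensus clustering chose k = ", subtyping$chosen_k,
            "; the signature stages use the 2-cluster grouping")
    d <- stats::as.dist(1 - subtyping$consensus[[1L]])
    labels2 <- stats::cutree(stats::hclust(d, method = "average"), k = 2L)
  } else {
    labels2 <- subtyping$labels
  }
  # orient labels so cluster "II" is the higher-HOX (poor prognosis) group
  mean_hox <- colMeans(expr[hox, , drop = FALSE])
  lev <- if (mean(mean_hox[labels2 == 1L]) <= mean(mean_hox[labels2 == 2L])) {
    c("I", "II")
  } else c("II", "I")
  subtype <- factor(lev[labels2], levels = c("I", "II"))

  deg <- differential_expression(expr, subtype,
                                 p_threshold = cfg$p_threshold,
                                 lfc_threshold = cfg$lfc_threshold)
  deg_genes <- deg_filter(deg, cfg$p_threshold, cfg$lfc_threshold)
  if (length(deg_genes) == 0L) {
    stop("pipeline aborted at stage 'deg': no gene passed the screen",
         call. = FALSE)
  }

  split <- split_cohort(colnames(expr), seed = seed + 202L)
  tr <- match(split$train, colnames(expr))
  te <- match(split$test, colnames(expr))

  target_n <- min(cfg$target_n, length(deg_genes))
  if (target_n < cfg$target_n) {
    warning("only ", length(deg_genes), " DEGs available; target_n lowered")
  }
  sig <- derive_signature(expr[deg_genes, tr, drop = FALSE], subtype[tr],
                          survival = clinical[tr, c("os_months", "os_event")],
                          target_n = target_n, n_trees = cfg$n_trees,
                          drop_fraction = cfg$drop_fraction,
                          tolerance = cfg$tolerance, seed = seed + 303L)

  evaluation <- list(
    train = evaluate_signature(sig, expr[, tr, drop = FALSE], subtype[tr],
                               clinical[tr, ]),
    test = evaluate_signature(sig, expr[, te, drop = FALSE], subtype[te],
                              clinical[te, ])
  )
  if (!is.null(cfg$external)) {
    ext <- .resolve_cohort(list(cohort = cfg$external))
    ext_expr <- ext$expression
    if (!is.null(ext$batch) && nlevels(factor(ext$batch)) > 1L) {
      ext_expr <- batch_standardize(ext_expr, ext$batch)
    }
    ext_calls <- classify_samples(ext_expr, sig)
    lr <- if (nlevels(droplevels(ext_calls$risk)) == 2L) {
      logrank_test(ext$clinical$os_months, ext$clinical$os_event,
                   ext_calls$risk)
    } else list(chi_square = NA_real_, p_value = NA_real_)
    evaluation$external <- list(logrank_p = lr$p_value,
                                n_low = sum(ext_calls$risk == "low"),
                                n_high = sum(ext_calls$risk == "high"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("hoxsig")),
    seed = seed,
    stage_seeds = c(subtype = seed + 101L, split = seed + 202L,
                    signature = seed + 303L),
    parameters = cfg[c("k_range", "n_iter", "subsample_fraction",
                       "p_threshold", "lfc_threshold", "n_trees",
                       "drop_fraction", "target_n", "tolerance")],
    n_samples = ncol(expr),
    chosen_k = subtyping$chosen_k,
    subtype_sizes = as.list(table(subtype)),
    n_deg = length(deg_genes),
    split_sizes = lengths(split),
    signature_genes = sig$genes,
    evaluation = evaluation
  )

  out <- structure(list(subtyping = subtyping, subtype = subtype,
                        deg = deg, deg_genes = deg_genes, split = split,
                        signature = sig, evaluation = evaluation,
                        manifest = manifest),
                   class = "hox_pipeline")
  if (!is.null(cfg$out_dir)) .write_pipeline_outputs(out, expr, clinical,
                                                     cfg$out_dir)
  out
}

#' @export
print.hox_pipeline <- function(x, ...) {
  m <- x$manifest
  cat("HOX subtype/signature pipeline (seed", m$seed, ")\n")
  cat("  samples:", m$n_samples, " chosen k:", m$chosen_k,
      " subtype I/II:", m$subtype_sizes[["I"]], "/",
      m$subtype_sizes[["II"]], "\n")
  cat("  DEGs:", m$n_deg, " split:", m$split_sizes[["train"]], "train /",
      m$split_sizes[["test"]], "test\n")
  cat("  signature:", paste(m$signature_genes, collapse = ", "), "\n")
  cat(sprintf("  AUC train %.3f / test %.3f",
              x$evaluation$train$auc, x$evaluation$test$auc))
  if (!is.null(x$evaluation$external)) {
    cat(sprintf("; external log-rank p %.3g",
                x$evaluation$external$logrank_p))
  }
  cat("\n")
  invisible(x)
}

.resolve_cohort <- function(cfg) {
  if (!is.null(cfg$cohort)) {
    ch <- cfg$cohort
    if (inherits(ch, "cohort_spec")) ch <- generate_cohort(ch)
    if (!inherits(ch, "synthetic_cohort")) {
      stop("'cohort' must be a synthetic_cohort or cohort_spec",
           call. = FALSE)
    }
    return(list(expression = ch$expression, clinical = ch$clinical,
                batch = ch$batch))
  }
  if (is.null(cfg$expression) || is.null(cfg$clinical)) {
    stop("config needs either 'cohort' or 'expression' + 'clinical'",
         call. = FALSE)
  }
  list(expression = cfg$expression, clinical = cfg$clinical,
       batch = cfg$batch)
}

.write_pipeline_outputs <- function(res, expr, clinical, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  clin <- clinical
  clin$subtype <- as.character(res$subtype)
  write_clinical(clin, file.path(dir, "clinical_with_subtype.tsv"))
  utils::write.table(res$deg, file.path(dir, "deg_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res$signature$subset_metrics,
                     file.path(dir, "subset_metrics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  calls <- classify_samples(expr, res$signature)
  utils::write.table(calls, file.path(dir, "risk_calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(genes = res$signature$genes,
         low_centroid = res$signature$low_centroid,
         high_centroid = res$signature$high_centroid,
         schema = "centroid_signature/1"),
    file.path(dir, "signature.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' Apply the published five-gene classifier to an expression matrix
#'
#' Classifies every sample of a cohort with [published_classifier()]. The
#' matrix must contain all five signature genes; missing genes are an error
#' naming them.
#'
#' @param matrix gene-by-sample log2 expression matrix (zero samples allowed;
#'   the result is then empty).
#' @return risk-call data frame as in [classify_samples()].
#' @export
apply_published <- function(matrix) {
  sig <- published_classifier()
  missing <- setdiff(sig$genes, rownames(matrix))
  if (length(missing)) {
    stop("signature gene(s) missing from the matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (ncol(matrix) == 0L) {
    return(data.frame(sample_id = character(0), dic_low = numeric(0),
                      dic_high = numeric(0),
                      risk = factor(character(0), levels = c("low", "high")),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  classify_samples(matrix, sig)
}
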