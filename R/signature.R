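## Derivation of the nearest-centroid risk signature: iterative random-forest
## gene elimination, exhaustive subset enumeration, two-centroid fitting,
## Euclidean-distance risk classification, and optimal-subset selection.

#' Iterative random-forest gene elimination
#'
#' Repeatedly trains a random forest (default 1000 trees, permutation
#' importance) predicting the subtype from the retained genes, then discards
#' the `floor(drop_fraction * m)` genes of lowest importance — clamped so the
#' retained count never falls below `target_n` (if a full drop would
#' undershoot, exactly `m - target_n` genes are discarded). Stops when
#' `target_n` genes remain. With 27 genes and the default third, the
#' retained sizes are 27, 18, 12, 9.
#'
#' @param matrix gene-by-sample log2 expression matrix restricted to the
#'   candidate (DEG) genes.
#' @param labels per-sample two-group subtype labels.
#' @param n_trees trees per forest.
#' @param drop_fraction fraction of genes discarded per round.
#' @param target_n number of genes to retain.
#' @param seed RNG seed (forests are seeded per round; deterministic).
#' @return object of class `elimination_trace`: list with `rounds` (each a
#'   list of `retained_genes`, `importance`, `oob_error`) and `final_genes`.
#' @export
rf_iterative_elimination <- function(matrix, labels, n_trees = 1000L,
                                     drop_fraction = 1 / 3, target_n = 9L,
                                     seed = 1L) {
  .check_expression_matrix(matrix)
  f <- .two_group_factor(labels, ncol(matrix))
  target_n <- .check_count(target_n, "target_n")
  n_trees <- .check_count(n_trees, "n_trees")
  .check_prob(drop_fraction, "drop_fraction", lo_open = TRUE, hi_open = TRUE)
  if (nrow(matrix) < target_n) {
    stop("fewer genes (", nrow(matrix), ") than target_n (", target_n, ")",
         call. = FALSE)
  }
  retained <- rownames(matrix)
  rounds <- list()
  round_i <- 0L
  while (length(retained) > target_n) {
    round_i <- round_i + 1L
    x <- t(matrix[retained, , drop = FALSE])
    fit <- ranger::ranger(x = x, y = f, num.trees = n_trees,
                          importance = "permutation",
                          seed = seed + round_i)
    imp <- fit$variable.importance[retained]
    m <- length(retained)
    n_drop <- min(floor(drop_fraction * m), m - target_n)
    # lowest-importance genes go; ties broken by position for determinism
    ord <- order(imp, seq_along(imp))
    drop <- retained[ord[seq_len(n_drop)]]
    rounds[[round_i]] <- list(retained_genes = retained,
                              importance = imp,
                              oob_error = fit$prediction.error)
    retained <- setdiff(retained, drop)
  }
  structure(list(rounds = rounds, final_genes = retained),
            class = "elimination_trace")
}

#' @export
print.elimination_trace <- function(x, ...) {
  sizes <- c(vapply(x$rounds, function(r) length(r$retained_genes),
                    integer(1)), length(x$final_genes))
  cat("Random-forest elimination:", paste(sizes, collapse = " -> "),
      "genes\n")
  if (length(x$rounds)) {
    cat("  OOB error by round:",
        paste(sprintf("%.3f", vapply(x$rounds, `[[`, numeric(1),
                                     "oob_error")), collapse = ", "), "\n")
  }
  cat("  final genes:", paste(x$final_genes, collapse = ", "), "\n")
  invisible(x)
}

#' Enumerate all nonempty gene subsets
#'
#' Returns the 2^m - 1 nonempty subsets of `genes` in deterministic order:
#' by size, then lexicographically by member positions. Guarded at m <= 20.
#'
#' @param genes character vector (1 to 20 genes).
#' @return list of character vectors.
#' @examples
#' length(enumerate_subsets(letters[1:9]))  # 511
#' @export
enumerate_subsets <- function(genes) {
  m <- length(genes)
  if (m < 1L) stop("need at least one gene", call. = FALSE)
  if (m > 20L) {
    stop("refusing to enumerate 2^", m, " - 1 subsets; cap the candidate ",
         "list at 20 genes (e.g. via rf_iterative_elimination)",
         call. = FALSE)
  }
  out <- vector("list", 2^m - 1)
  i <- 0L
  for (size in seq_len(m)) {
    combos <- utils::combn(m, size)
    for (j in seq_len(ncol(combos))) {
      i <- i + 1L
      out[[i]] <- genes[combos[, j]]
    }
  }
  out
}

## internal constructor
new_centroid_signature <- function(genes, low_centroid, high_centroid,
                                   ...) {
  stopifnot(length(genes) == length(low_centroid),
            length(genes) == length(high_centroid),
            all(is.finite(low_centroid)), all(is.finite(high_centroid)))
  structure(list(genes = as.character(genes),
                 low_centroid = stats::setNames(as.numeric(low_centroid),
                                                genes),
                 high_centroid = stats::setNames(as.numeric(high_centroid),
                                                 genes),
                 ...),
            class = "centroid_signature")
}

#' Build a two-centroid signature from labelled samples
#'
#' The low-risk centroid is the per-gene mean expression over the
#' good-prognosis group and the high-risk centroid over the poor-prognosis
#' group, restricted to `gene_subset`.
#'
#' @param matrix gene-by-sample log2 expression matrix.
#' @param risk_groups per-sample labels with exactly two levels; the first
#'   level is the low-risk (good-prognosis) group.
#' @param gene_subset genes to include; all must be present in the matrix.
#' @return a `centroid_signature`.
#' @export
build_centroids <- function(matrix, risk_groups, gene_subset) {
  .check_expression_matrix(matrix)
  f <- .two_group_factor(risk_groups, ncol(matrix), "risk_groups")
  missing <- setdiff(gene_subset, rownames(matrix))
  if (length(missing)) {
    stop("gene(s) absent from the matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sub <- matrix[gene_subset, , drop = FALSE]
  low <- rowMeans(sub[, f == levels(f)[1L], drop = FALSE])
  high <- rowMeans(sub[, f == levels(f)[2L], drop = FALSE])
  new_centroid_signature(gene_subset, low, high)
}

#' @export
print.centroid_signature <- function(x, ...) {
  cat("Nearest-centroid risk signature over", length(x$genes), "genes\n")
  tab <- data.frame(gene = x$genes, low = round(x$low_centroid, 2),
                    high = round(x$high_centroid, 2))
  print(tab, row.names = FALSE)
  if (!is.null(x$metrics)) {
    cat(sprintf("training AUC %.3f", x$metrics$auc))
    if (!is.null(x$metrics$logrank_p)) {
      cat(sprintf(", log-rank p %.3g", x$metrics$logrank_p))
    }
    cat("\n")
  }
  invisible(x)
}

#' @export
summary.centroid_signature <- function(object, ...) {
  print(object)
  if (!is.null(object$subset_metrics)) {
    cat("\nSelected from", nrow(object$subset_metrics),
        "candidate subsets; top 5 by AUC:\n")
    top <- object$subset_metrics[order(-object$subset_metrics$auc), ]
    print(utils::head(top[, c("subset", "size", "auc")], 5),
          row.names = FALSE)
  }
  invisible(object)
}

#' Classify samples by Euclidean distance to the risk centroids
#'
#' For each sample, computes the Euclidean distance between its expression
#' over the signature genes and the low-risk and high-risk centroids. A
#' sample is low-risk iff it is strictly closer to the low-risk centroid;
#' ties go to high-risk. The continuous risk score is
#' `dic_low - dic_high` (higher = more high-risk-like).
#'
#' @param x either a sample-by-gene numeric matrix whose columns are the
#'   signature genes (in signature order), or a gene-by-sample expression
#'   matrix with rownames covering the signature genes.
#' @param signature a `centroid_signature`.
#' @return data frame with `sample_id`, `dic_low`, `dic_high`, `risk`
#'   (factor low/high), `score`.
#' @examples
#' sig <- published_classifier()
#' v <- c(1.61, 4.55, 0.74, 1.62, 0.43)
#' classify_samples(rbind(s1 = v), sig)  # dic_low = 1, risk = low
#' @export
classify_samples <- function(x, signature) {
  if (!inherits(signature, "centroid_signature")) {
    stop("'signature' must be a centroid_signature", call. = FALSE)
  }
  genes <- signature$genes
  if (is.numeric(x) && is.null(dim(x))) x <- rbind(sample1 = x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("'x' must be a numeric matrix or vector", call. = FALSE)
  }
  if (!is.null(colnames(x)) && all(genes %in% colnames(x))) {
    x <- x[, genes, drop = FALSE]          # sample-by-gene input
  } else if (!is.null(rownames(x)) && all(genes %in% rownames(x))) {
    x <- t(x[genes, , drop = FALSE])       # gene-by-sample input
  } else if (ncol(x) != length(genes)) {
    named <- c(colnames(x), rownames(x))
    if (!is.null(named) && any(genes %in% named)) {
      stop("signature gene(s) missing from the input: ",
           paste(setdiff(genes, named), collapse = ", "), call. = FALSE)
    }
    stop("dimension mismatch: expected the ", length(genes),
         " signature genes", call. = FALSE)
  }
  if (!all(is.finite(x))) stop("non-finite expression values",
                               call. = FALSE)
  dl <- sqrt(rowSums(sweep(x, 2L, signature$low_centroid)^2))
  dh <- sqrt(rowSums(sweep(x, 2L, signature$high_centroid)^2))
  ids <- rownames(x)
  if (is.null(ids)) ids <- sprintf("sample%d", seq_len(nrow(x)))
  data.frame(
    sample_id = ids,
    dic_low = unname(dl),
    dic_high = unname(dh),
    risk = factor(ifelse(dl < dh, "low", "high"), levels = c("low", "high")),
    score = unname(dl - dh),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' @rdname classify_samples
#' @param object a `centroid_signature`.
#' @param newdata expression input as in `x`.
#' @param ... unused.
#' @export
predict.centroid_signature <- function(object, newdata, ...) {
  classify_samples(newdata, object)
}

#' Evaluate a signature against subtype labels and survival
#'
#' Computes the AUC of the continuous risk score (`dic_low - dic_high`)
#' for discriminating the second (poor-prognosis) subtype level, the
#' log-rank p-value between the predicted risk groups, and the group sizes.
#' If every sample lands in one risk group the log-rank test is skipped
#' (`logrank_p = NA`, `logrank_skipped = TRUE`).
#'
#' @param signature a `centroid_signature`.
#' @param matrix gene-by-sample expression matrix.
#' @param subtype_labels per-sample two-group labels (second level =
#'   positive class).
#' @param survival optional data frame with `os_months` and `os_event`
#'   aligned to the samples.
#' @return list with `auc`, `logrank_p`, `logrank_skipped`, `n_low`,
#'   `n_high`.
#' @export
evaluate_signature <- function(signature, matrix, subtype_labels,
                               survival = NULL) {
  f <- .two_group_factor(subtype_labels, ncol(matrix), "subtype_labels")
  calls <- classify_samples(matrix, signature)
  auc <- roc_auc(calls$score, f == levels(f)[2L])
  n_low <- sum(calls$risk == "low")
  n_high <- sum(calls$risk == "high")
  logrank_p <- NA_real_
  skipped <- TRUE
  if (!is.null(survival) && n_low > 0L && n_high > 0L) {
    lr <- logrank_test(survival$os_months, survival$os_event, calls$risk)
    logrank_p <- lr$p_value
    skipped <- FALSE
  }
  list(auc = auc, logrank_p = logrank_p, logrank_skipped = skipped,
       n_low = n_low, n_high = n_high)
}

#' Select the optimal signature from per-subset metrics
#'
#' Among subsets whose AUC is within `tolerance` of the maximum, returns the
#' smallest; ties resolve to the higher AUC, then to the lexicographically
#' first gene list.
#'
#' @param metrics data frame with columns `subset` (comma-joined gene
#'   names), `size`, `auc`.
#' @param tolerance AUC slack below the maximum (default 0.01).
#' @return the selected row of `metrics`.
#' @export
select_optimal_signature <- function(metrics, tolerance = 0.01) {
  if (nrow(metrics) == 0L) stop("no candidate subsets", call. = FALSE)
  eligible <- metrics[metrics$auc >= max(metrics$auc) - tolerance, ,
                      drop = FALSE]
  ord <- order(eligible$size, -eligible$auc, eligible$subset)
  eligible[ord[1L], , drop = FALSE]
}

#' Derive a nearest-centroid risk signature from a labelled cohort
#'
#' The end-to-end derivation: random-forest iterative elimination reduces
#' the candidate genes to `target_n`, every nonempty subset of the survivors
#' is fitted as a two-centroid classifier (low-risk centroid = subtype-I
#' mean profile, high-risk = subtype-II), each subset is scored by training
#' AUC, and the smallest subset within `tolerance` of the best AUC is
#' returned as the fitted signature.
#'
#' @param matrix gene-by-sample log2 expression matrix restricted to the
#'   candidate (e.g. DEG) genes.
#' @param labels per-sample subtype labels (first level = good prognosis /
#'   low risk).
#' @param survival optional data frame with `os_months`, `os_event` for
#'   log-rank evaluation of the fitted signature.
#' @param target_n genes retained by elimination (default 9).
#' @param n_trees,drop_fraction elimination parameters.
#' @param tolerance AUC slack for [select_optimal_signature()].
#' @param seed RNG seed.
#' @return a `centroid_signature` with extra fields: `trace` (the
#'   elimination trace), `subset_metrics` (all-subset AUC table), and
#'   `metrics` (training evaluation of the selected signature).
#' @seealso [predict.centroid_signature()], [published_classifier()]
#' @export
derive_signature <- function(matrix, labels, survival = NULL,
                             target_n = 9L, n_trees = 1000L,
                             drop_fraction = 1 / 3, tolerance = 0.01,
                             seed = 1L) {
  f <- .two_group_factor(labels, ncol(matrix))
  trace <- if (nrow(matrix) > target_n) {
    rf_iterative_elimination(matrix, f, n_trees = n_trees,
                             drop_fraction = drop_fraction,
                             target_n = target_n, seed = seed)
  } else {
    structure(list(rounds = list(), final_genes = rownames(matrix)),
              class = "elimination_trace")
  }
  subsets <- enumerate_subsets(trace$final_genes)
  rows <- lapply(subsets, function(gs) {
    sig <- build_centroids(matrix, f, gs)
    ev <- evaluate_signature(sig, matrix, f, survival = NULL)
    data.frame(subset = paste(gs, collapse = ","),
               size = length(gs), auc = ev$auc,
               stringsAsFactors = FALSE)
  })
  metrics <- do.call(rbind, rows)
  best <- select_optimal_signature(metrics, tolerance = tolerance)
  genes <- strsplit(best$subset, ",", fixed = TRUE)[[1L]]
  sig <- build_centroids(matrix, f, genes)
  sig$trace <- trace
  sig$subset_metrics <- metrics
  sig$metrics <- evaluate_signature(sig, matrix, f, survival = survival)
  sig
}
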