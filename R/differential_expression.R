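#' Per-gene two-group differential expression
#'
#' Welch two-sample t-test on log2 expression for every gene, comparing the
#' second factor level of `labels` against the first. `log2fc` is the group
#' II minus group I mean (the matrix is already on the log2 scale, so a mean
#' difference is a log2 fold change). Benjamini-Hochberg q-values are
#' reported alongside the raw p-values used for screening.
#'
#' A gene that is constant within both groups gets `p = 1` when the group
#' means agree and `p = 0` when they differ (zero-variance limit).
#'
#' @param matrix gene-by-sample log2 expression matrix.
#' @param labels per-sample two-group labels; the second factor level plays
#'   the role of the comparison (subtype II) group. Both groups need at
#'   least 2 samples.
#' @param p_threshold,lfc_threshold screening thresholds applied to the
#'   `passes` flag: raw `p < p_threshold` and `|log2fc| > lfc_threshold`,
#'   both strict.
#' @return data frame with one row per gene: `gene_id`, `log2fc`, `p_value`,
#'   `q_value`, `passes`, in the matrix's gene order.
#' @examples
#' m <- rbind(g1 = c(1, 2, 3, 5, 6, 7))
#' colnames(m) <- paste0("s", 1:6)
#' differential_expression(m, rep(c("I", "II"), each = 3))
#' @export
differential_expression <- function(matrix, labels,
                                    p_threshold = 0.01, lfc_threshold = 1) {
  .check_expression_matrix(matrix)
  f <- .two_group_factor(labels, ncol(matrix))
  g1 <- which(f == levels(f)[1L])
  g2 <- which(f == levels(f)[2L])
  if (length(g1) < 2L || length(g2) < 2L) {
    stop("both groups need at least 2 samples", call. = FALSE)
  }
  n1 <- length(g1); n2 <- length(g2)
  x1 <- matrix[, g1, drop = FALSE]
  x2 <- matrix[, g2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  diff <- m2 - m1
  tstat <- diff / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  zero <- se2 == 0
  p[zero] <- ifelse(diff[zero] == 0, 1, 0)
  q <- stats::p.adjust(p, method = "BH")
  data.frame(
    gene_id = rownames(matrix),
    log2fc = diff,
    p_value = p,
    q_value = q,
    passes = p < p_threshold & abs(diff) > lfc_threshold,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Filter a differential-expression table to significant genes
#'
#' Keeps genes with raw `p_value < p_threshold` and `|log2fc| >
#' lfc_threshold` (both strict), preserving gene order.
#'
#' @param records data frame from [differential_expression()].
#' @param p_threshold,lfc_threshold positive screening thresholds (defaults
#'   0.01 and 1).
#' @return character vector of passing gene IDs.
#' @export
deg_filter <- function(records, p_threshold = 0.01, lfc_threshold = 1) {
  if (p_threshold <= 0 || lfc_threshold <= 0) {
    stop("thresholds must be positive", call. = FALSE)
  }
  if (nrow(records) == 0L) return(character(0))
  keep <- records$p_value < p_threshold & abs(records$log2fc) > lfc_threshold
  records$gene_id[keep]
}
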