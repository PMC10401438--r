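#' Single-sample pathway activity score
#'
#' For a gene set of m genes present in the matrix, each sample's score is
#' the sum of the genes' normalized expression divided by the square root
#' of m. "Normalized" means the per-gene z-score across the cohort (each
#' gene centered to its cohort mean and scaled by its cohort SD); genes with
#' zero variance contribute 0. Set members absent from the matrix are
#' dropped with a warning; a set with no present members is an error.
#'
#' @param matrix gene-by-sample log2 expression matrix.
#' @param gene_set character vector of gene identifiers (nonempty, unique).
#' @return named numeric vector of per-sample scores.
#' @examples
#' m <- rbind(a = c(1, 2, 3), b = c(3, 2, 1))
#' colnames(m) <- paste0("s", 1:3)
#' pathway_activity_score(m, c("a", "b"))
#' @export
pathway_activity_score <- function(matrix, gene_set) {
  .check_expression_matrix(matrix)
  gene_set <- unique(as.character(gene_set))
  if (length(gene_set) == 0L) stop("empty gene set", call. = FALSE)
  present <- gene_set[gene_set %in% rownames(matrix)]
  absent <- setdiff(gene_set, present)
  if (length(present) == 0L) {
    stop("no gene-set member present in the matrix", call. = FALSE)
  }
  if (length(absent)) {
    warning("dropping ", length(absent), " absent gene(s): ",
            paste(utils::head(absent, 5), collapse = ", "))
  }
  sub <- matrix[present, , drop = FALSE]
  s <- apply(sub, 1L, stats::sd)
  z <- (sub - rowMeans(sub)) / ifelse(s == 0, 1, s)
  z[s == 0, ] <- 0
  colSums(z) / sqrt(length(present))
}

#' Compare pathway activity scores between two groups
#'
#' Wilcoxon rank-sum comparison of each gene set's per-sample scores between
#' the two groups, with the direction of the difference.
#'
#' @param matrix gene-by-sample log2 expression matrix.
#' @param gene_sets named list of gene sets.
#' @param labels per-sample two-group labels (second level = comparison
#'   group).
#' @param alternative passed to [wilcoxon_rank_sum()] (default two-sided).
#' @return data frame with `set`, `statistic`, `p_value`,
#'   `direction` (`"up"` if the second group's median score is higher).
#' @export
compare_pathway_scores <- function(matrix, gene_sets, labels,
                                   alternative = "two.sided") {
  f <- .two_group_factor(labels, ncol(matrix))
  rows <- lapply(names(gene_sets), function(nm) {
    sc <- pathway_activity_score(matrix, gene_sets[[nm]])
    x <- sc[f == levels(f)[1L]]
    y <- sc[f == levels(f)[2L]]
    w <- wilcoxon_rank_sum(y, x, alternative = alternative)
    data.frame(set = nm, statistic = w$statistic, p_value = w$p_value,
               direction = if (stats::median(y) >= stats::median(x)) "up"
                           else "down",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
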