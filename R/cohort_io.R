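## Reading/writing the cohort bundle and the fixed transforms: log2 with a
## pseudocount, per-batch standardization, the 2:1 train/test split, and the
## CNV / mutation-count rules.

#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects gene rows and sample columns, with a header row of sample IDs and
#' the gene identifier in the first column. Duplicated identifiers,
#' non-numeric cells and empty matrices are errors.
#'
#' @param path file path.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE, fill = FALSE)
  if (nrow(tab) == 0L || ncol(tab) < 2L) {
    stop("expression file '", path, "' contains no genes or no samples",
         call. = FALSE)
  }
  genes <- as.character(tab[[1L]])
  if (anyDuplicated(genes)) {
    dups <- unique(genes[duplicated(genes)])
    first_line <- which(genes %in% dups)[1L] + 1L  # +1 for the header
    stop("duplicated gene identifier(s) ", paste(dups, collapse = ", "),
         " (first at line ", first_line, ")", call. = FALSE)
  }
  vals <- tab[, -1L, drop = FALSE]
  bad <- which(!vapply(vals, is.numeric, logical(1)))
  if (length(bad)) {
    stop("non-numeric expression values in column(s): ",
         paste(names(vals)[bad], collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  .check_expression_matrix(m)
  m
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression()]; round-trips exactly up to numeric
#' formatting (15 significant digits).
#'
#' @param matrix gene-by-sample numeric matrix with dimnames.
#' @param path output file path.
#' @export
write_expression <- function(matrix, path) {
  .check_expression_matrix(matrix)
  tab <- data.frame(gene = rownames(matrix), matrix, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(format(tab, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a clinical table
#'
#' The clinical TSV has one row per sample with columns `sample_id`,
#' `age_at_diagnosis`, `sex`, `who_grade`, `histology`, `os_months`,
#' `os_event`.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_clinical <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, fill = FALSE)
  need <- c("sample_id", "os_months", "os_event")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("clinical table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(tab$sample_id)) stop("duplicated sample_id in clinical table",
                                         call. = FALSE)
  if (any(tab$os_months < 0)) stop("negative os_months", call. = FALSE)
  if (!all(tab$os_event %in% c(0L, 1L))) stop("os_event must be 0/1",
                                              call. = FALSE)
  tab
}

#' @rdname read_clinical
#' @param clinical data frame as returned by [read_clinical()].
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Log2-transform raw expression values
#'
#' `log2(raw + pseudocount)`, elementwise. Raw values must be nonnegative
#' and the pseudocount positive.
#'
#' @param raw nonnegative numeric matrix or vector.
#' @param pseudocount positive offset added before the logarithm.
#' @return transformed values, same shape as `raw`.
#' @examples
#' log2_transform(c(0, 3, 1023))  # 0, 2, 10
#' @export
log2_transform <- function(raw, pseudocount = 1) {
  if (!is.numeric(raw)) stop("'raw' must be numeric", call. = FALSE)
  if (any(raw < 0, na.rm = TRUE)) stop("'raw' contains negative values",
                                       call. = FALSE)
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L ||
      pseudocount <= 0) {
    stop("'pseudocount' must be a single positive number", call. = FALSE)
  }
  log2(raw + pseudocount)
}

#' Standardize expression within batches
#'
#' Within each batch, centers every gene to mean zero and scales it to unit
#' variance (genes with zero within-batch variance are scaled by 1), then
#' restores each gene's global mean and SD so the output stays on the log2
#' expression scale. Removes additive and multiplicative batch effects; it
#' is not an empirical-Bayes batch correction.
#'
#' @param matrix gene-by-sample numeric matrix.
#' @param batch per-sample batch labels; every batch needs at least two
#'   samples.
#' @return corrected matrix, same dimensions and dimnames.
#' @export
batch_standardize <- function(matrix, batch) {
  .check_expression_matrix(matrix)
  if (length(batch) != ncol(matrix)) {
    stop("'batch' length must equal the number of samples", call. = FALSE)
  }
  batch <- factor(batch)
  sizes <- table(batch)
  if (any(sizes < 2L)) {
    stop("singleton batch(es): ", paste(names(sizes)[sizes < 2L],
                                        collapse = ", "), call. = FALSE)
  }
  g_mean <- rowMeans(matrix)
  g_sd <- apply(matrix, 1L, stats::sd)
  g_sd[g_sd == 0] <- 1
  out <- matrix
  for (b in levels(batch)) {
    idx <- which(batch == b)
    sub <- matrix[, idx, drop = FALSE]
    m <- rowMeans(sub)
    s <- apply(sub, 1L, stats::sd)
    s[s == 0] <- 1
    out[, idx] <- (sub - m) / s
  }
  out * g_sd + g_mean
}

#' Split a cohort 2:1 into training and testing sets
#'
#' The training share is `floor(n * train_parts / (train_parts +
#' test_parts))`; with the default 2:1 ratio, 571 samples give 380 training
#' and 191 testing samples. The partition is a seeded random permutation:
#' disjoint, exhaustive, and reproducible.
#'
#' @param sample_ids character vector of at least three unique sample IDs.
#' @param seed RNG seed.
#' @param train_parts,test_parts the ratio (defaults 2:1).
#' @return list with `train` and `test` character vectors.
#' @examples
#' sp <- split_cohort(sprintf("S%03d", 1:571), seed = 1)
#' lengths(sp)  # 380, 191
#' @export
split_cohort <- function(sample_ids, seed, train_parts = 2L, test_parts = 1L) {
  sample_ids <- as.character(sample_ids)
  n <- length(sample_ids)
  if (n < 3L) stop("need at least 3 samples to split", call. = FALSE)
  if (anyDuplicated(sample_ids)) stop("duplicated sample IDs", call. = FALSE)
  n_train <- floor(n * train_parts / (train_parts + test_parts))
  with_seed(seed, {
    perm <- sample(sample_ids)
    list(train = sort(perm[seq_len(n_train)]),
         test = sort(perm[-seq_len(n_train)]))
  })
}

#' CNV segment mean from an absolute copy number
#'
#' `log2(copy_number / 2)`: zero for diploid, positive for gains, negative
#' for losses.
#'
#' @param copy_number positive copy number.
#' @return segment mean (log2 ratio).
#' @examples
#' segment_mean(c(2, 4, 1))  # 0, 1, -1
#' @export
segment_mean <- function(copy_number) {
  if (!is.numeric(copy_number) || any(!is.finite(copy_number)) ||
      any(copy_number <= 0)) {
    stop("'copy_number' must be positive and finite", call. = FALSE)
  }
  log2(copy_number / 2)
}

#' Call the CNV state of a segment
#'
#' Gain if the segment mean is strictly greater than `gain`, loss if
#' strictly less than `loss`, otherwise neutral; the boundary values
#' themselves are neutral.
#'
#' @param segment_mean finite numeric vector of segment means (log2 ratio).
#' @param gain,loss thresholds (defaults +0.2 / -0.2).
#' @return factor with levels `loss`, `neutral`, `gain`.
#' @examples
#' call_cnv_state(c(0.3, 0.2, -0.25))  # gain, neutral, loss
#' @export
call_cnv_state <- function(segment_mean, gain = 0.2, loss = -0.2) {
  if (any(!is.finite(segment_mean))) stop("segment means must be finite",
                                          call. = FALSE)
  if (loss >= gain) stop("'loss' threshold must be below 'gain'",
                         call. = FALSE)
  out <- ifelse(segment_mean > gain, "gain",
                ifelse(segment_mean < loss, "loss", "neutral"))
  factor(out, levels = c("loss", "neutral", "gain"))
}

#' Mutation frequency as a percentage
#'
#' `100 * n_mutated / n_total`.
#'
#' @param n_mutated number of mutated samples (0..n_total).
#' @param n_total total number of samples (> 0).
#' @return percentage.
#' @examples
#' mutation_frequency(26, 453)  # 5.74
#' @export
mutation_frequency <- function(n_mutated, n_total) {
  if (!is.numeric(n_mutated) || !is.numeric(n_total) ||
      any(n_total <= 0) || any(n_mutated < 0) || any(n_mutated > n_total)) {
    stop("require 0 <= n_mutated <= n_total and n_total > 0", call. = FALSE)
  }
  100 * n_mutated / n_total
}

#' Read / write gene sets in GMT format
#'
#' GMT: one tab-separated line per set — name, description, then members.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) stop("malformed GMT line ", bad[1L],
                        " (need name, description, >=1 gene)", call. = FALSE)
  sets <- lapply(fields, function(f) f[-c(1L, 2L)])
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("gene sets must be named", call. = FALSE)
  }
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a synthetic cohort bundle to a directory
#'
#' Writes `expression.tsv`, `clinical.tsv`, `cnv_segments.tsv` (0-based
#' half-open coordinates) and `mutation_counts.tsv`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if absent).
#' @return invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "synthetic_cohort")) {
    stop("'cohort' must be a synthetic_cohort", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  write_clinical(cohort$clinical, file.path(dir, "clinical.tsv"))
  utils::write.table(cohort$cnv_segments, file.path(dir, "cnv_segments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = colnames(cohort$expression),
               mutation_count = cohort$mutation_count),
    file.path(dir, "mutation_counts.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
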