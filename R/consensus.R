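## Resampling consensus clustering over a feature submatrix (typically the
## 39 HOX genes), with PAC and CDF delta-area statistics for choosing the
## number of clusters.

#' Resampling consensus clustering
#'
#' For each candidate cluster number k, repeatedly subsamples the samples
#' (without replacement), clusters each subsample with seeded k-means on
#' per-gene standardized values, and records for every sample pair the
#' fraction of co-sampled runs in which the pair co-clustered. Cluster-number
#' selection uses the proportion of ambiguous clustering (PAC, minimized)
#' with the CDF delta-area reported for inspection; final labels come from
#' hierarchical grouping (average linkage) of `1 - consensus` distances.
#'
#' @param matrix feature-by-sample numeric matrix (at least 2 features);
#'   typically the expression submatrix of the HOX genes.
#' @param k_range ascending integer vector of candidate cluster counts.
#' @param n_iter resampling iterations per k.
#' @param subsample_fraction fraction of samples drawn per iteration.
#' @param seed RNG seed; results are deterministic given the seed.
#' @param base_clusterer function `(x, k)` returning an integer vector of
#'   cluster labels for the rows of `x`; defaults to seeded
#'   [stats::kmeans()].
#' @return an object of class `consensus_result`: list with `k_range`,
#'   `consensus` (named list of sample-by-sample matrices in \[0, 1\] with
#'   unit diagonal), `cdf` (ecdf functions of the off-diagonal entries),
#'   `delta_area`, `pac`, `chosen_k`, and `labels` (integer vector in
#'   `1..chosen_k`, named by sample).
#' @examples
#' set.seed(1)
#' x <- cbind(matrix(rnorm(40, 0), 2), matrix(rnorm(40, 5), 2))
#' colnames(x) <- paste0("s", 1:40); rownames(x) <- c("g1", "g2")
#' cc <- consensus_cluster(x, k_range = 2:3, n_iter = 50, seed = 1)
#' cc$chosen_k
#' @export
consensus_cluster <- function(matrix, k_range = 2:6, n_iter = 1000L,
                              subsample_fraction = 0.8, seed = 1L,
                              base_clusterer = NULL) {
  .check_expression_matrix(matrix)
  if (nrow(matrix) < 2L) stop("need at least 2 feature genes", call. = FALSE)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2L)) stop("k_range entries must be >= 2", call. = FALSE)
  n <- ncol(matrix)
  if (n < max(k_range) * 2L) {
    stop("need at least 2 x max(k_range) samples", call. = FALSE)
  }
  .check_prob(subsample_fraction, "subsample_fraction", lo_open = TRUE)
  n_iter <- .check_count(n_iter, "n_iter")

  # per-gene standardization for the base clusterer
  s <- apply(matrix, 1L, stats::sd)
  if (all(s == 0)) {
    warning("all samples identical on the feature genes; ",
            "returning a single cluster")
    cons1 <- matrix(1, n, n, dimnames = list(colnames(matrix),
                                             colnames(matrix)))
    return(structure(list(
      k_range = k_range,
      consensus = stats::setNames(rep(list(cons1), length(k_range)),
                                  paste0("k", k_range)),
      cdf = NULL, delta_area = NULL,
      pac = stats::setNames(rep(0, length(k_range)), paste0("k", k_range)),
      chosen_k = 1L,
      labels = stats::setNames(rep(1L, n), colnames(matrix))
    ), class = "consensus_result"))
  }
  z <- (matrix - rowMeans(matrix)) / ifelse(s == 0, 1, s)
  x <- t(z)  # samples in rows for clustering

  if (is.null(base_clusterer)) {
    base_clusterer <- function(xx, k) {
      stats::kmeans(xx, centers = k, nstart = 1L, iter.max = 100L)$cluster
    }
  }
  n_sub <- ceiling(subsample_fraction * n)

  consensus <- vector("list", length(k_range))
  names(consensus) <- paste0("k", k_range)
  never <- FALSE
  with_seed(seed, {
    for (ki in seq_along(k_range)) {
      k <- k_range[ki]
      co_sampled <- matrix(0, n, n)
      co_clustered <- matrix(0, n, n)
      for (it in seq_len(n_iter)) {
        idx <- sample.int(n, n_sub)
        cl <- base_clusterer(x[idx, , drop = FALSE], k)
        ind <- outer(cl, cl, "==")
        co_sampled[idx, idx] <- co_sampled[idx, idx] + 1
        co_clustered[idx, idx] <- co_clustered[idx, idx] + ind
      }
      cons <- ifelse(co_sampled > 0, co_clustered / pmax(co_sampled, 1), 0)
      if (any(co_sampled == 0 & row(co_sampled) != col(co_sampled))) {
        never <- TRUE
      }
      diag(cons) <- 1
      dimnames(cons) <- list(colnames(matrix), colnames(matrix))
      consensus[[ki]] <- cons
    }
  })
  if (never) {
    warning("some sample pairs were never co-sampled; ",
            "their consensus entries are 0")
  }

  pac <- vapply(consensus, pac_score, numeric(1))
  names(pac) <- paste0("k", k_range)
  delta <- if (length(consensus) >= 2L) cdf_delta_area(consensus) else NULL
  cdf <- lapply(consensus, function(m) stats::ecdf(m[upper.tri(m)]))
  chosen_k <- select_k(pac, k_range)

  d <- stats::as.dist(1 - consensus[[paste0("k", chosen_k)]])
  hc <- stats::hclust(d, method = "average")
  labels <- stats::cutree(hc, k = chosen_k)

  structure(list(
    k_range = k_range, consensus = consensus, cdf = cdf,
    delta_area = delta, pac = pac, chosen_k = chosen_k,
    labels = labels
  ), class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("Consensus clustering over k =", paste(x$k_range, collapse = ", "),
      "\n")
  if (!is.null(x$pac)) {
    cat("  PAC:", paste(sprintf("%s=%.3f", names(x$pac), x$pac),
                        collapse = "  "), "\n")
  }
  cat("  chosen k:", x$chosen_k, " cluster sizes:",
      paste(table(x$labels), collapse = "/"), "\n")
  invisible(x)
}

#' @export
plot.consensus_result <- function(x, ...) {
  if (is.null(x$cdf)) {
    warning("degenerate result; nothing to plot")
    return(invisible(x))
  }
  grid <- seq(0, 1, length.out = 201)
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "consensus index", ylab = "CDF",
                 main = "Consensus CDF per k", ...)
  for (i in seq_along(x$cdf)) {
    graphics::lines(grid, x$cdf[[i]](grid), col = i)
  }
  graphics::legend("bottomright", legend = names(x$cdf),
                   col = seq_along(x$cdf), lty = 1, bty = "n")
  invisible(x)
}

#' Proportion of ambiguous clustering (PAC)
#'
#' Fraction of off-diagonal consensus entries strictly between `lower` and
#' `upper`. Lower PAC indicates a more stable clustering.
#'
#' @param consensus symmetric consensus matrix with entries in \[0, 1\].
#' @param lower,upper ambiguity window (defaults 0.1, 0.9).
#' @return proportion in \[0, 1\].
#' @export
pac_score <- function(consensus, lower = 0.1, upper = 0.9) {
  if (lower >= upper) stop("'lower' must be below 'upper'", call. = FALSE)
  off <- consensus[upper.tri(consensus)]
  if (length(off) == 0L) return(0)
  mean(off > lower & off < upper)
}

#' CDF delta-area across candidate cluster numbers
#'
#' For each k, computes the area under the empirical CDF of the off-diagonal
#' consensus entries over \[0, 1\] (step-function integral), then the
#' relative change: the smallest k reports its own area, each later k
#' reports `(A(k) - A(k-1)) / A(k-1)`.
#'
#' @param consensus_list list of consensus matrices in ascending-k order
#'   (at least 2).
#' @return named numeric vector of delta-area values.
#' @export
cdf_delta_area <- function(consensus_list) {
  if (length(consensus_list) < 2L) {
    stop("need consensus matrices for at least 2 values of k", call. = FALSE)
  }
  areas <- vapply(consensus_list, function(m) {
    .cdf_area(m[upper.tri(m)])
  }, numeric(1))
  delta <- numeric(length(areas))
  delta[1L] <- areas[1L]
  for (i in seq_along(areas)[-1L]) {
    delta[i] <- if (areas[i - 1L] > 0) {
      (areas[i] - areas[i - 1L]) / areas[i - 1L]
    } else 0
  }
  names(delta) <- names(consensus_list)
  delta
}

## area under the empirical CDF of values in [0,1]:
## integral of the right-continuous step function over [0, 1]
.cdf_area <- function(v) {
  v <- sort(v)
  n <- length(v)
  if (n == 0L) return(0)
  xs <- c(v, 1)
  f <- seq_len(n) / n
  sum(diff(xs) * f)
}

#' Select the cluster number by minimum PAC
#'
#' Returns the k minimizing PAC; ties resolve to the smallest k.
#'
#' @param pac numeric PAC values aligned with `k_range`.
#' @param k_range candidate cluster counts.
#' @return the chosen k.
#' @export
select_k <- function(pac, k_range) {
  if (length(pac) != length(k_range)) {
    stop("'pac' and 'k_range' lengths differ", call. = FALSE)
  }
  k_range[which.min(pac)]  # which.min takes the first (smallest k) on ties
}

#' PCA projection of samples
#'
#' Principal component scores of the per-gene standardized matrix, for
#' low-dimensional visualization of subtype structure. Component signs are
#' fixed so the loading of largest magnitude is positive.
#'
#' @param matrix feature-by-sample numeric matrix.
#' @param n_components number of components to return.
#' @return sample-by-component score matrix.
#' @export
pca_project <- function(matrix, n_components = 3L) {
  .check_expression_matrix(matrix)
  n_components <- .check_count(n_components, "n_components")
  if (n_components > min(dim(matrix))) {
    stop("'n_components' exceeds matrix dimensions", call. = FALSE)
  }
  s <- apply(matrix, 1L, stats::sd)
  z <- (matrix - rowMeans(matrix)) / ifelse(s == 0, 1, s)
  p <- stats::prcomp(t(z), center = FALSE, scale. = FALSE)
  k <- n_components
  rot <- p$rotation[, seq_len(k), drop = FALSE]
  scores <- p$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(rot[, j]))
    if (rot[i_max, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  scores
}
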