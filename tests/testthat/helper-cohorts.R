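# Shared fixtures, built in code at test time.

# a small cohort with clear two-subtype structure
small_cohort <- function(n = 60, n_genes = 200, n_de = 30, seed = 3,
                         ...) {
  hox <- hox_gene_list()
  if (n_genes < length(hox) + n_de + 10) hox <- hox[1:5]
  generate_cohort(cohort_spec(n_samples = n, n_genes = n_genes,
                              n_de_genes = n_de, hox_gene_names = hox,
                              seed = seed, ...))
}

# tiny labelled expression matrix: g genes x (n1 + n2) samples, the second
# group shifted by `delta` on the first `n_shifted` genes
toy_matrix <- function(g = 5, n1 = 4, n2 = 4, delta = 0, n_shifted = g,
                       seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(g * (n1 + n2)), nrow = g,
              dimnames = list(paste0("g", seq_len(g)),
                              paste0("s", seq_len(n1 + n2))))
  if (n_shifted > 0) {
    m[seq_len(n_shifted), n1 + seq_len(n2)] <-
      m[seq_len(n_shifted), n1 + seq_len(n2)] + delta
  }
  attr(m, "groups") <- rep(c("I", "II"), c(n1, n2))
  m
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# exhaustive two-group permutation p-value for the log-rank statistic:
# fraction of equal-size relabelings whose statistic is at least as extreme
logrank_permutation_p <- function(times, events, groups) {
  f <- factor(groups)
  n <- length(times)
  idx1 <- which(f == levels(f)[1])
  k <- length(idx1)
  obs <- logrank_test(times, events, groups)$chi_square
  combos <- utils::combn(n, k)
  stats <- apply(combos, 2, function(ix) {
    g <- rep("B", n); g[ix] <- "A"
    logrank_test(times, events, g)$chi_square
  })
  mean(stats >= obs - 1e-12)
}

# exact Wilcoxon p by full enumeration of rank assignments (no ties)
wilcoxon_enumeration_p <- function(x, y,
                                   alternative = c("two.sided", "less")) {
  alternative <- match.arg(alternative)
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  us <- apply(combos, 2, function(ix) sum(r[ix]) - nx * (nx + 1) / 2)
  if (alternative == "less") {
    mean(us <= u_obs)
  } else {
    mean_u <- nx * ny / 2
    mean(abs(us - mean_u) >= abs(u_obs - mean_u) - 1e-12)
  }
}

# brute-force AUC over all positive-negative pairs
auc_bruteforce <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}
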