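test_that("PAC counts ambiguous off-diagonal entries", {
  stable <- matrix(c(1, 0, 1, 0,
                     0, 1, 0, 1,
                     1, 0, 1, 0,
                     0, 1, 0, 1), 4, 4)
  expect_equal(pac_score(stable), 0)
  fuzzy <- matrix(0.5, 3, 3); diag(fuzzy) <- 1
  expect_equal(pac_score(fuzzy), 1)
  # 2 of the 6 upper-triangle entries ambiguous -> 1/3
  m <- diag(4)
  m[upper.tri(m)] <- c(0, 1, 0.5, 1, 0.4, 0)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  expect_equal(pac_score(m), 1 / 3)
  expect_error(pac_score(m, lower = 0.9, upper = 0.1), "lower")
})

test_that("CDF delta-area matches manual step-function integration", {
  mk <- function(vals) {
    # 4x4 symmetric matrix whose 6 upper-triangle entries are `vals`
    m <- diag(4)
    m[upper.tri(m)] <- vals
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  }
  # entries (0.2, 0.2, 0.4, 0.6, 0.6, 1):
  # CDF steps: F=2/6 on [0.2,0.4), 3/6 on [0.4,0.6), 5/6 on [0.6,1)
  # area = 0.2*(2/6) + 0.2*(3/6) + 0.4*(5/6) = 1/15 + 1/10 + 1/3 = 0.5
  a <- mk(c(0.2, 0.2, 0.4, 0.6, 0.6, 1))
  # entries (0, 0, 0, 1, 1, 1): area = 0.5 * 1 + 0.5 * ... = 1*?:
  # F = 3/6 on [0,1), so area = 1 * 0.5 = 0.5... use distinct second matrix
  b <- mk(c(0, 0, 0, 0, 1, 1))  # F = 4/6 on [0,1) -> area = 2/3
  delta <- cdf_delta_area(list(k2 = a, k3 = b))
  expect_equal(delta[["k2"]], 0.5)
  expect_equal(delta[["k3"]], (2 / 3 - 0.5) / 0.5)
  # identical matrices for successive k give delta 0 beyond the first
  delta2 <- cdf_delta_area(list(k2 = a, k3 = a, k4 = a))
  expect_equal(unname(delta2[2:3]), c(0, 0))
})

test_that("k selection minimizes PAC with ties to the smaller k", {
  expect_equal(select_k(c(0.05, 0.30), 2:3), 2)
  expect_equal(select_k(c(0.30, 0.05), 2:3), 3)
  expect_equal(select_k(c(0.1, 0.1, 0.2), 2:4), 2)
})

test_that("consensus equals single-run co-membership when subsampling is off", {
  ch <- small_cohort(n = 30, n_genes = 60, n_de = 10, seed = 12)
  m <- ch$expression[1:10, ]
  # deterministic base clusterer: cut on the first feature's median
  det <- function(x, k) as.integer(x[, 1] > stats::median(x[, 1])) + 1L
  cc <- consensus_cluster(m, k_range = 2, n_iter = 25,
                          subsample_fraction = 1, seed = 1,
                          base_clusterer = det)
  cl <- det(scale(t(m)), 2)
  cons <- cc$consensus$k2
  expect_true(all(cons %in% c(0, 1)))
  expect_equal(unname(cons), outer(cl, cl, "==") * 1)
})

test_that("a single full-sample iteration gives a 0/1 consensus matrix", {
  ch <- small_cohort(n = 24, n_genes = 60, n_de = 10, seed = 4)
  cc <- consensus_cluster(ch$expression[1:8, ], k_range = 2, n_iter = 1,
                          subsample_fraction = 1, seed = 2)
  expect_true(all(cc$consensus$k2 %in% c(0, 1)))
})

test_that("identical samples give a warning and a single cluster", {
  m <- matrix(1, nrow = 3, ncol = 10,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:10)))
  expect_warning(cc <- consensus_cluster(m, k_range = 2:3, n_iter = 5,
                                         seed = 1), "single cluster")
  expect_equal(cc$chosen_k, 1L)
  expect_true(all(cc$labels == 1L))
})

test_that("well-separated subtypes are recovered with the chosen k = 2", {
  ch <- generate_cohort(cohort_spec(n_samples = 120, n_genes = 200,
                                    n_de_genes = 40, hox_shift = 3,
                                    seed = 21))
  hox <- intersect(hox_gene_list(), rownames(ch$expression))
  cc <- consensus_cluster(ch$expression[hox, ], k_range = 2:4,
                          n_iter = 200, seed = 5)
  expect_equal(cc$chosen_k, 2)
  expect_gte(ari(cc$labels, ch$true_subtype), 0.9)
  # consensus matrices are symmetric with unit diagonal, entries in [0,1]
  for (m in cc$consensus) {
    expect_equal(m, t(m))
    expect_true(all(diag(m) == 1))
    expect_true(all(m >= 0 & m <= 1))
  }
  # determinism
  cc2 <- consensus_cluster(ch$expression[hox, ], k_range = 2:4,
                           n_iter = 200, seed = 5)
  expect_identical(cc$consensus, cc2$consensus)
})

test_that("PCA projection fixes signs and orders variance", {
  ch <- small_cohort(n = 40, n_genes = 100, n_de = 20, seed = 13)
  sc <- pca_project(ch$expression, n_components = 3)
  expect_equal(dim(sc), c(40L, 3L))
  v <- apply(sc, 2, var)
  expect_true(all(diff(v) <= 1e-8))
  # data on a line: only one component with appreciable variance
  t_line <- seq(0, 1, length.out = 20)
  line <- rbind(g1 = 2 * t_line, g2 = -t_line + 1, g3 = 3 * t_line)
  colnames(line) <- paste0("s", 1:20)
  sc_line <- pca_project(line, n_components = 3)
  v_line <- apply(sc_line, 2, var)
  expect_gt(v_line[1], 1e-6)
  expect_lt(v_line[2] / v_line[1], 1e-10)
})
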