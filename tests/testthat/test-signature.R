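test_that("elimination shrinks 27 -> 18 -> 12 -> 9 and stops at target", {
  ch <- small_cohort(n = 50, n_genes = 100, n_de = 30, seed = 15)
  m <- ch$expression[ch$true_de_genes[1:27], ]
  tr <- rf_iterative_elimination(m, ch$true_subtype, n_trees = 100,
                                 target_n = 9, seed = 1)
  sizes <- vapply(tr$rounds, function(r) length(r$retained_genes),
                  integer(1))
  expect_equal(sizes, c(27L, 18L, 12L))
  expect_length(tr$final_genes, 9)
  # strictly shrinking and nested
  for (i in seq_along(tr$rounds)[-1]) {
    expect_true(all(tr$rounds[[i]]$retained_genes %in%
                      tr$rounds[[i - 1]]$retained_genes))
  }
  # m = target: zero rounds, identity
  tr0 <- rf_iterative_elimination(m[1:9, ], ch$true_subtype,
                                  n_trees = 50, target_n = 9, seed = 1)
  expect_length(tr0$rounds, 0)
  expect_identical(tr0$final_genes, rownames(m)[1:9])
  expect_error(rf_iterative_elimination(m[1:5, ], ch$true_subtype,
                                        target_n = 9), "fewer genes")
  # deterministic given the seed
  tr2 <- rf_iterative_elimination(m, ch$true_subtype, n_trees = 100,
                                  target_n = 9, seed = 1)
  expect_identical(tr$final_genes, tr2$final_genes)
})

test_that("informative genes survive elimination among null genes", {
  # 3 strongly informative genes planted among 30 nulls, across seeds
  wins <- 0L
  for (s in 1:5) {
    ch <- generate_cohort(cohort_spec(
      n_samples = 150, n_genes = 100, n_de_genes = 3, de_shift = 2,
      hox_shift = 0, seed = 100 + s))
    genes <- c(ch$true_de_genes, sprintf("G%05d", 1:30))
    tr <- rf_iterative_elimination(ch$expression[genes, ],
                                   ch$true_subtype, n_trees = 500,
                                   target_n = 3, seed = s)
    if (setequal(tr$final_genes, ch$true_de_genes)) wins <- wins + 1L
  }
  expect_gte(wins, 5L)
})

test_that("subset enumeration has the right cardinality and order", {
  expect_length(enumerate_subsets(letters[1:9]), 511)
  expect_length(enumerate_subsets("a"), 1)
  expect_length(enumerate_subsets(letters[1:3]), 7)
  s3 <- enumerate_subsets(c("x", "y", "z"))
  expect_identical(s3, list("x", "y", "z", c("x", "y"), c("x", "z"),
                            c("y", "z"), c("x", "y", "z")))
  for (m in c(1, 5, 12)) {
    subs <- enumerate_subsets(paste0("g", seq_len(m)))
    expect_length(subs, 2^m - 1)
    expect_false(anyDuplicated(vapply(subs, paste, "", collapse = ",")) > 0)
  }
  expect_error(enumerate_subsets(paste0("g", 1:21)), "20")
})

test_that("centroids are group means and reproduce the reference fixture", {
  # one sample per group: centroids equal the samples themselves
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  rownames(m) <- paste0("g", 1:3)
  sig1 <- build_centroids(m, factor(c("low", "high"),
                                    levels = c("low", "high")), rownames(m))
  expect_equal(unname(sig1$low_centroid), c(1, 2, 3))
  expect_equal(unname(sig1$high_centroid), c(4, 5, 6))
  # a matrix whose group means equal the published centroids round-trips
  pub <- published_classifier()
  low <- pub$low_centroid; high <- pub$high_centroid
  mm <- cbind(l1 = low - 0.5, l2 = low + 0.5,
              h1 = high - 1, h2 = high + 1)
  rownames(mm) <- pub$genes
  sig2 <- build_centroids(mm, factor(c("I", "I", "II", "II")), pub$genes)
  expect_equal(sig2$low_centroid, low)
  expect_equal(sig2$high_centroid, high)
  # permuting samples leaves the centroids unchanged
  perm <- c(3, 1, 4, 2)
  sig3 <- build_centroids(mm[, perm],
                          factor(c("I", "I", "II", "II"))[perm], pub$genes)
  expect_equal(sig3$low_centroid, sig2$low_centroid)
  expect_error(build_centroids(mm, factor(c("I", "I", "II", "II")),
                               c("HOXA6", "NOPE")), "NOPE")
})

test_that("risk calls follow the Euclidean rule with ties to high risk", {
  sig <- published_classifier()
  at_high <- classify_samples(rbind(sig$high_centroid), sig)
  expect_equal(at_high$dic_high, 0)
  expect_equal(as.character(at_high$risk), "high")
  midway <- classify_samples(rbind((sig$low_centroid + sig$high_centroid)
                                   / 2), sig)
  expect_equal(midway$dic_low, midway$dic_high)
  expect_equal(as.character(midway$risk), "high")
  # unit distance from the low centroid on the first gene
  v <- c(1.61, 4.55, 0.74, 1.62, 0.43)
  call <- classify_samples(v, sig)
  expect_equal(call$dic_low, 1.0)
  expect_equal(as.character(call$risk), "low")
  expect_error(classify_samples(c(1, 2, 3), sig), "dimension mismatch")
})

test_that("classification is invariant to squaring the distance and flips under centroid swap", {
  sig <- published_classifier()
  set.seed(16)
  for (i in 1:50) {
    v <- runif(5, 0, 9)
    call <- classify_samples(v, sig)
    sq_low <- sum((v - sig$low_centroid)^2)
    sq_high <- sum((v - sig$high_centroid)^2)
    expect_equal(as.character(call$risk),
                 if (sq_low < sq_high) "low" else "high")
    swapped <- hoxsig:::new_centroid_signature(
      sig$genes, sig$high_centroid, sig$low_centroid)
    if (call$dic_low != call$dic_high) {
      expect_false(as.character(classify_samples(v, swapped)$risk) ==
                     as.character(call$risk))
    }
  }
})

test_that("signature evaluation scores discrimination and survival", {
  ch <- generate_cohort(cohort_spec(n_samples = 300, n_genes = 300,
                                    n_de_genes = 60, hox_shift = 2,
                                    seed = 17))
  sig <- build_centroids(ch$expression, ch$true_subtype,
                         c("HOXA6", "HOXC4", "HOXC5", "HOXC6"))
  ev <- evaluate_signature(sig, ch$expression, ch$true_subtype,
                           ch$clinical)
  expect_gte(ev$auc, 0.9)
  expect_lt(ev$logrank_p, 0.05)
  expect_equal(ev$n_low + ev$n_high, 300)
  # swapping the centroids mirrors the AUC
  swapped <- hoxsig:::new_centroid_signature(
    sig$genes, sig$high_centroid, sig$low_centroid)
  ev_sw <- evaluate_signature(swapped, ch$expression, ch$true_subtype)
  expect_equal(ev_sw$auc, 1 - ev$auc, tolerance = 1e-12)
  # a random-gene signature on a null cohort sits near AUC 0.5
  null_ch <- generate_cohort(cohort_spec(
    n_samples = 300, n_genes = 300, n_de_genes = 60,
    hox_shift = 0, de_shift = 0, subtype_hr = 1, seed = 18))
  set.seed(19)
  null_sig <- build_centroids(null_ch$expression,
                              sample(rep(c("a", "b"), 150)),
                              sprintf("G%05d", 1:5))
  ev_null <- evaluate_signature(null_sig, null_ch$expression,
                                null_ch$true_subtype)
  expect_lt(abs(ev_null$auc - 0.5), 0.1)
})

test_that("optimal-subset selection balances size against accuracy", {
  one <- data.frame(subset = "a", size = 1, auc = 0.8)
  expect_identical(select_optimal_signature(one)$subset, "a")
  two <- data.frame(subset = c("a,b,c,d,e", "a,b,c,d,e,f,g,h,i"),
                    size = c(5, 9), auc = c(0.95, 0.955))
  expect_identical(select_optimal_signature(two, 0.01)$subset, "a,b,c,d,e")
  expect_identical(select_optimal_signature(two, 0)$subset,
                   "a,b,c,d,e,f,g,h,i")
  ties <- data.frame(subset = c("b", "a"), size = c(1, 1),
                     auc = c(0.9, 0.9))
  expect_identical(select_optimal_signature(ties)$subset, "a")
})

test_that("derivation recovers planted signature genes end to end", {
  hits <- 0L
  for (s in 1:3) {
    ch <- generate_cohort(cohort_spec(
      n_samples = 400, n_genes = 500, n_de_genes = 5, de_shift = 1.3,
      hox_shift = 0, seed = 200 + s))
    deg <- deg_filter(differential_expression(ch$expression,
                                              ch$true_subtype))
    sp <- split_cohort(colnames(ch$expression), seed = s)
    tr_idx <- match(sp$train, colnames(ch$expression))
    sig <- derive_signature(ch$expression[deg, tr_idx, drop = FALSE],
                            ch$true_subtype[tr_idx],
                            target_n = min(9, length(deg)),
                            n_trees = 300, seed = s)
    if (length(intersect(sig$genes, ch$true_de_genes)) >= 4) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 3L)
})
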