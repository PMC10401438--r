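test_that("Kaplan-Meier matches closed forms and the empirical survivor", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))
  # all censored: no event rows, S identically 1
  expect_equal(nrow(km_estimate(c(1, 2, 3), c(0, 0, 0))), 0)
  # no censoring: product-limit equals the empirical survival function
  set.seed(6)
  tt <- rexp(40)
  km2 <- km_estimate(tt, rep(1, 40))
  emp <- sapply(km2$time, function(s) mean(tt > s))
  expect_equal(km2$surv, emp)
  # mixed small example against a hand product-limit computation:
  # times 1(event) 2(cens) 3(event) 4(event):
  # S(1)=3/4; S(3)=3/4*1/2=3/8; S(4)=0
  km3 <- km_estimate(c(1, 2, 3, 4), c(1, 0, 1, 1))
  expect_equal(km3$surv, c(3 / 4, 3 / 8, 0))
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
})

test_that("log-rank is null-calibrated, symmetric, and robust to no-event groups", {
  set.seed(7)
  tt <- rexp(20); ev <- rbinom(20, 1, 0.7)
  dup <- logrank_test(c(tt, tt), c(ev, ev), rep(c("a", "b"), each = 20))
  expect_lt(dup$chi_square, 1e-10)
  expect_gt(dup$p_value, 0.99)
  g <- rep(c("a", "b"), 10)
  expect_equal(logrank_test(tt, ev, g),
               logrank_test(tt, ev, ifelse(g == "a", "b", "a")))
  # a group with zero events is still defined
  ev0 <- ev; ev0[g == "a"] <- 0
  expect_no_error(logrank_test(tt, ev0, g))
})

test_that("log-rank p agrees with the exhaustive permutation null at n = 8", {
  set.seed(8)
  tt <- c(2, 5, 7, 9, 12, 16, 20, 25)
  ev <- c(1, 1, 0, 1, 1, 1, 0, 1)
  g <- rep(c("a", "b"), 4)
  obs <- logrank_test(tt, ev, g)
  p_perm <- logrank_permutation_p(tt, ev, g)
  expect_lt(abs(obs$p_value - p_perm), 0.15)
})

test_that("Cox recovers planted effects and flags bad designs", {
  ch <- generate_cohort(cohort_spec(n_samples = 600, n_genes = 50,
                                    n_de_genes = 10, subtype_hr = 2.2,
                                    seed = 14))
  x <- as.integer(ch$true_subtype == "II")
  fit <- cox_ph(data.frame(subtype = x),
                ch$clinical$os_months, ch$clinical$os_event)
  expect_lt(abs(fit$hr - 2.2) / 2.2, 0.2)
  expect_true(fit$ci_low <= fit$hr && fit$hr <= fit$ci_high)
  expect_error(cox_ph(data.frame(a = x, b = x),
                      ch$clinical$os_months, ch$clinical$os_event),
               "collinear")
  expect_error(cox_ph(data.frame(a = rep(1, 600)),
                      ch$clinical$os_months, ch$clinical$os_event),
               "constant")
})

test_that("Wilcoxon switches between exact and approximate correctly", {
  # one-sided exact p = 1/6 over the 6 rank assignments
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4),
                                 alternative = "less")$p_value, 1 / 6)
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4),
                                 alternative = "less")$p_value,
               wilcoxon_enumeration_p(c(1, 2), c(3, 4), "less"))
  # exact path equals full enumeration at n1 = n2 = 7
  set.seed(9)
  x <- rnorm(7); y <- rnorm(7) + 0.8
  expect_equal(wilcoxon_rank_sum(x, y)$p_value,
               wilcoxon_enumeration_p(x, y), tolerance = 1e-12)
  # the approximate path (min n > 8) stays within 0.005 of the exact law
  x9 <- rnorm(9); y9 <- rnorm(9) + 0.8
  approx_p <- wilcoxon_rank_sum(x9, y9)$p_value
  exact_p <- stats::wilcox.test(x9, y9, exact = TRUE)$p.value
  expect_lt(abs(approx_p - exact_p), 0.005)
  # identical multisets: two-sided p = 1
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
})

test_that("chi-square follows the Pearson formula", {
  even <- chi_square_test(matrix(10, 2, 2))
  expect_equal(even$statistic, 0)
  expect_equal(even$p_value, 1)
  diag40 <- chi_square_test(rbind(c(20, 0), c(0, 20)))
  expect_equal(diag40$statistic, 40)
  tab <- rbind(c(12, 5, 8), c(3, 9, 6))
  expect_equal(chi_square_test(tab)$statistic,
               chi_square_test(t(tab))$statistic)
  expect_equal(chi_square_test(tab)$df, 2)
  expect_error(chi_square_test(rbind(c(0, 0), c(1, 2))), "margin")
})

test_that("AUC equals brute-force pair counting and flips under negation", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(1, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  set.seed(11)
  s <- rnorm(6); l <- c(1, 0, 1, 0, 0, 1)
  expect_equal(roc_auc(s, l), auc_bruteforce(s, l))
  expect_equal(roc_auc(s, l) + roc_auc(-s, l), 1)
  s_tied <- c(1, 1, 2, 3, 3, 4)
  expect_equal(roc_auc(s_tied, l), auc_bruteforce(s_tied, l))
  expect_error(roc_auc(s, rep(1, 6)), "both classes")
})
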