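# Second-level statistics: tau-a, randomization test, Wilcoxon, transforms,
# repeated-measures interaction, Bonferroni.

test_that("kendall_tau_a handles ties as neither concordant nor discordant", {
  x <- c(1, 2, 2, 3); y <- c(1, 3, 2, 2)
  expect_equal(kendall_tau_a(x, y), 2 / 6)
  expect_equal(kendall_tau_a(1:7, 1:7), 1)
  expect_equal(kendall_tau_a(1:7, 7:1), -1)
  expect_error(kendall_tau_a(1:3, 1:4), "length mismatch")
})

test_that("kendall_tau_a equals the pair-enumeration oracle on tied vectors", {
  set.seed(10)
  for (i in 1:25) {
    m <- sample(5:60, 1)
    x <- sample(1:8, m, replace = TRUE)     # heavy ties
    y <- sample(1:8, m, replace = TRUE)
    expect_equal(kendall_tau_a(x, y), tau_a_oracle(x, y))
  }
})

test_that("randomization test matches the exact label-permutation null at n = 4", {
  a <- random_rdm(4, seed = 1)
  b <- random_rdm(4, seed = 2)
  exact_null <- randomization_exact_oracle(unclass(a), unclass(b))
  obs <- kendall_tau_a(rdm_vec(a), rdm_vec(b))
  p_exact <- mean(exact_null >= obs - 1e-12)
  res <- randomization_test(a, b, n_iter = 4999, seed = 3)
  expect_equal(res$tau_a, obs)
  expect_lt(abs(res$p - p_exact), 0.05)
  # b = a: observed tau is the maximum, p bounded by the exact tail of 1
  self_null <- randomization_exact_oracle(unclass(a), unclass(a))
  p_self <- mean(self_null >= max(self_null) - 1e-12)
  res_self <- randomization_test(a, a, n_iter = 999, seed = 4)
  expect_lt(res_self$p, p_self + 0.05)
  expect_error(randomization_test(a, rdm(matrix(0.5, 4, 4) - diag(0.5, 4),
                                         labels = rdm_labels(a), measure = "other")),
               "tau undefined")
})

test_that("randomization p is invariant to consistent relabeling and deterministic", {
  a <- random_rdm(8, seed = 5)
  b <- random_rdm(8, seed = 6)
  p1 <- randomization_test(a, b, n_iter = 500, seed = 7)
  p2 <- randomization_test(a, b, n_iter = 500, seed = 7)
  expect_identical(p1$p, p2$p)                  # determinism contract
  perm <- sample(rdm_labels(a))
  ap <- rdm_align(a, perm); bp <- rdm_align(b, perm)
  p3 <- randomization_test(ap, bp, n_iter = 500, seed = 7)
  expect_equal(p3$tau_a, p1$tau_a)
  expect_lt(abs(p3$p - p1$p), 0.06)             # same null law, same seed stream
})

test_that("one-sided Wilcoxon matches exact sign-pattern enumeration", {
  expect_equal(as.numeric(wilcoxon_signed_rank_one_sided(c(1, 2, 3, 4, 5, 6))),
               1 / 64)                          # all positive, n = 6
  # antisymmetric pairs -> p near 0.5
  v <- c(-3, 3, -1, 1, -2, 2)
  expect_equal(as.numeric(wilcoxon_signed_rank_one_sided(v)),
               wilcoxon_exact_oracle(v), tolerance = 1e-12)
  expect_lt(abs(as.numeric(wilcoxon_signed_rank_one_sided(v)) - 0.5), 0.2)
  # n = 16 random values vs enumeration, tie-free exact path
  set.seed(20)
  for (i in 1:5) {
    v16 <- rnorm(16) + 0.4
    expect_equal(as.numeric(wilcoxon_signed_rank_one_sided(v16)),
                 wilcoxon_exact_oracle(v16), tolerance = 1e-6)
  }
  # tied data stay exact via the generating-function convolution
  vt <- c(2, 2, 2, -1, 1, 3, 3, -2, 4, 4, 1, -1, 2, 5, 5, 3)
  expect_equal(as.numeric(wilcoxon_signed_rank_one_sided(vt)),
               wilcoxon_exact_oracle(vt), tolerance = 1e-12)
  # the convolution oracle itself agrees with enumeration where both run
  expect_equal(wilcoxon_conv_oracle(vt), wilcoxon_exact_oracle(vt),
               tolerance = 1e-12)
  # beyond the exact range the tie-corrected normal approximation is close
  set.seed(21)
  v30 <- sample(c(-3:-1, 1:5), 30, replace = TRUE)
  expect_lt(abs(as.numeric(wilcoxon_signed_rank_one_sided(v30)) -
                  wilcoxon_conv_oracle(v30)), 0.01)
  expect_error(wilcoxon_signed_rank_one_sided(rep(0, 6)), "zero")
  expect_error(wilcoxon_signed_rank_one_sided(c(1, 2, 3, 4)), "at least 5")
})

test_that("tau_to_r and fisher_z implement the transform chain", {
  expect_equal(tau_to_r(0), 0)
  expect_equal(tau_to_r(1), 1)
  expect_equal(tau_to_r(0.5), sin(pi / 4))
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(tau_to_r(0)), 0)
  # odd, strictly increasing, fixes {-1, 0, 1}
  g <- seq(-1, 1, by = 0.05)
  expect_equal(tau_to_r(-g), -tau_to_r(g))
  expect_true(all(diff(tau_to_r(g)) > 0))
  expect_equal(tau_to_r(c(-1, 0, 1)), c(-1, 0, 1))
  expect_error(fisher_z(1), "infinite")
  expect_error(tau_to_r(1.2), "tau")
})

test_that("2x2 repeated-measures interaction equals the squared paired t", {
  set.seed(30)
  n <- 12
  base <- rnorm(n)
  # additive table: row + column effects only -> F ~ 0
  add <- cbind(base + 1, base + 2, base + 3, base + 4)
  expect_lt(rm_anova_2x2(add)$F, 1e-20)
  # crossed interaction
  tab <- cbind(base + rnorm(n, 1), base + rnorm(n), base + rnorm(n),
               base + rnorm(n, 0.5))
  d <- (tab[, 1] - tab[, 2]) - (tab[, 3] - tab[, 4])
  t_oracle <- unname(t.test(d)$statistic)
  res <- rm_anova_2x2(tab)
  expect_equal(res$F, t_oracle^2, tolerance = 1e-10)
  expect_equal(res$df, c(1L, n - 1L))
  expect_equal(res$p, pf(t_oracle^2, 1, n - 1, lower.tail = FALSE))
  expect_error(rm_anova_2x2(tab[, 1:3]), "4 condition")
  expect_error(rm_anova_2x2(tab[1:2, ]), "3 subjects")
  tabNA <- tab; tabNA[1, 1] <- NA
  expect_error(rm_anova_2x2(tabNA), "missing")
})

test_that("bonferroni adjustment and critical alpha", {
  expect_equal(bonferroni_alpha(16), 0.003125)
  expect_equal(bonferroni(0.2, m = 1), 0.2)
  expect_equal(bonferroni(0.4, m = 4), 1)
  expect_equal(bonferroni(c(0.001, 0.02), m = 16), c(0.016, 0.32))
  expect_error(bonferroni(1.2, m = 2), "0, 1")
})

test_that("group_model_fit aggregates subject taus with Wilcoxon inference", {
  model <- random_rdm(8, seed = 40)
  subj <- replicate(7, model, simplify = FALSE)
  fit <- group_model_fit(subj, model, m = 4)
  expect_equal(unname(fit$mean_tau), 1)
  expect_equal(fit$p, 1 / 128)        # all-positive sign pattern, n = 7
  expect_true(fit$significant)        # 1/128 < 0.05/4
  expect_error(group_model_fit(subj[1:4], model), "at least 5")
  # mean tau increases with the mixture weight carrying the model
  mods <- make_model_rdms(12, seed = 41)
  mean_tau_at <- function(w) {
    cfg <- synthetic_config(n_objects = 12, n_subjects = 5, grid_dims = c(8, 8, 8),
                            regions = list(r1 = list(lo = c(1, 1, 1), hi = c(4, 4, 4),
                                                     weights = list(visual = c(w, 0),
                                                                    conceptual = c(w, 0)))),
                            noise_sd = 0.8, seed = 42)
    sim <- simulate_patterns(mods$V, mods$C, cfg)
    rdms <- lapply(names(sim$patterns), function(s)
      pattern_rdm(roi_patterns(sim, s, "visual", "r1")))
    group_model_fit(rdms, mods$V)$mean_tau
  }
  taus <- vapply(c(0, 0.4, 0.9), mean_tau_at, numeric(1))
  expect_true(all(diff(taus) > 0))
})
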