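# Synthetic-data generators: model RDM construction, pattern simulation,
# behavioral generators, BOLD simulation, reproducibility.

test_that("make_model_rdms builds near-orthogonal chained-pair models", {
  mods <- make_model_rdms(20, tol = 0.02, seed = 70)
  for (r in list(mods$V, mods$C)) {
    m <- unclass(r)
    expect_equal(m, t(m))
    expect_true(all(diag(m) == 0))
  }
  expect_lt(abs(mods$tau), 0.02)
  expect_equal(mods$tau, kendall_tau_a(rdm_vec(mods$V), rdm_vec(mods$C)))
  # every object has a low partner in V and a different low partner in C
  for (r in list(mods$V, mods$C)) {
    m <- unclass(r); diag(m) <- NA
    q10 <- quantile(m, 0.1, na.rm = TRUE)
    expect_true(all(apply(m, 1, min, na.rm = TRUE) <= q10))
  }
  vpart <- apply(`diag<-`(unclass(mods$V), NA), 1, which.min)
  cpart <- apply(`diag<-`(unclass(mods$C), NA), 1, which.min)
  expect_true(all(vpart != cpart))
  # determinism
  mods2 <- make_model_rdms(20, tol = 0.02, seed = 70)
  expect_identical(unclass(mods$V), unclass(mods2$V))
  expect_identical(unclass(mods$C), unclass(mods2$C))
})

test_that("simulate_patterns recovers the generating structure", {
  mods16 <- make_model_rdms(16, seed = 71)
  mods8 <- make_model_rdms(8, seed = 71)
  run_case <- function(wv, wc, noise_sd, seed, g = 8, mods = mods16) {
    n_obj <- nrow(mods$V)
    cfg <- synthetic_config(n_objects = n_obj, n_subjects = 1,
                            grid_dims = c(g, g, g),
                            regions = list(r1 = list(lo = c(1, 1, 1), hi = c(g, g, g),
                                                     weights = list(visual = c(wv, wc),
                                                                    conceptual = c(wv, wc)))),
                            noise_sd = noise_sd, seed = seed)
    sim <- simulate_patterns(mods$V, mods$C, cfg)
    r <- pattern_rdm(roi_patterns(sim, "s01", "visual", "r1"))
    c(v = kendall_tau_a(rdm_vec(r), rdm_vec(mods$V)),
      c = kendall_tau_a(rdm_vec(r), rdm_vec(mods$C)))
  }
  # visual-only region at vanishing noise approaches tau 1 on V (large voxel
  # count: recovery is limited by correlation sampling error, ~1/sqrt(nvox))
  ceiling_tau <- run_case(1, 0, 1e-4, 72, g = 32, mods = mods8)
  expect_gt(ceiling_tau["v"], 0.95)
  # no structure: both taus near zero across seeds
  null_taus <- t(vapply(1:8, function(s) run_case(0, 0, 1, 100 + s), numeric(2)))
  expect_lt(max(abs(colMeans(null_taus))), 0.05)
  # integrative region: both models recovered at the group level
  cfg <- synthetic_config(n_objects = 16, n_subjects = 8, grid_dims = c(8, 8, 8),
                          regions = list(prc = list(lo = c(1, 1, 1), hi = c(5, 5, 5),
                                                    weights = list(visual = c(0.5, 0.5),
                                                                   conceptual = c(0.5, 0.5)))),
                          noise_sd = 1, seed = 73)
  sim <- simulate_patterns(mods16$V, mods16$C, cfg)
  rdms <- lapply(names(sim$patterns), function(s)
    pattern_rdm(roi_patterns(sim, s, "conceptual", "prc")))
  fit_v <- group_model_fit(rdms, mods16$V)
  fit_c <- group_model_fit(rdms, mods16$C)
  expect_lt(fit_v$p, 0.05)
  expect_lt(fit_c$p, 0.05)
})

test_that("ratings round-trip the visual model and exclusion works end to end", {
  mods <- make_model_rdms(20, seed = 74)
  rt <- simulate_ratings(mods$V, noise_sd = 0, fail_fraction = 0, seed = 75)
  v <- visual_rdm(filter_raters(rt))
  expect_gt(kendall_tau_a(rdm_vec(v), rdm_vec(rdm_align(mods$V, rdm_labels(v)))),
            0.95)
  # a planted failing rater is removed and the result equals the clean table
  # with that rater's records excised by hand
  rt_fail <- simulate_ratings(mods$V, noise_sd = 0, fail_fraction = 1 / 15,
                              seed = 75)
  filtered <- filter_raters(rt_fail)
  expect_identical(attr(filtered, "excluded_raters"), "r01")
  by_hand <- rt_fail[rt_fail$rater != "r01", , drop = FALSE]
  class(by_hand) <- class(rt_fail)
  expect_equal(unclass(visual_rdm(filtered)), unclass(visual_rdm(by_hand)))
})

test_that("norms round-trip the conceptual model through filtering", {
  mods <- make_model_rdms(20, seed = 76)
  norms <- simulate_norms(mods$C, seed = 77)
  expect_true(all(norms$producer_count >= 1 & norms$producer_count <= 20))
  cfm <- filter_features(norms)
  expect_false(any(grepl("decoy|unreliable", colnames(cfm))))
  cr <- conceptual_rdm(cfm)
  expect_gt(kendall_tau_a(rdm_vec(cr), rdm_vec(rdm_align(mods$C, rdm_labels(cr)))),
            0.9)
})

test_that("embedding leak mixes visual structure monotonically", {
  mods <- make_model_rdms(20, seed = 78)
  tau_v <- vapply(c(0, 0.3, 0.6), function(leak) {
    er <- embedding_rdm(simulate_embeddings(mods$C, mods$V, leak = leak, seed = 79))
    kendall_tau_a(rdm_vec(er), rdm_vec(mods$V))
  }, numeric(1))
  expect_lt(abs(tau_v[1]), 0.08)      # leak 0: no visual structure
  expect_gt(tau_v[2], 0.1)            # leak 0.3: clearly positive
  expect_true(all(diff(tau_v) > 0))
  e <- simulate_embeddings(mods$C, mods$V, dim = 300, seed = 80)
  expect_equal(dim(e), c(20L, 300L))
  expect_equal(unname(sqrt(rowSums(e^2))), rep(1, 20), tolerance = 1e-10)
})

test_that("simulate_bold supports exact and unbiased beta recovery", {
  ev <- event_table(1, "conceptual", c("a", "b", "c"), onset = c(0, 16, 36))
  amp <- rbind(a = c(1, 2), b = c(3, -1), c = c(0, 1))
  sb0 <- simulate_bold(ev, amp, noise_sd = 0, n_volumes = 36)
  est0 <- estimate_patterns(sb0$ts, sb0$design)
  expect_equal(est0$beta, amp, tolerance = 1e-9, ignore_attr = TRUE)
  # unbiasedness across seeds
  errs <- vapply(1:40, function(s) {
    sb <- simulate_bold(ev, amp, noise_sd = 1, n_volumes = 36, seed = s)
    mean(estimate_patterns(sb$ts, sb$design)$beta - amp)
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.08)
  expect_error(simulate_bold(ev, amp, noise_sd = -1, n_volumes = 36),
               "nonnegative")
})

test_that("all generators are reproducible under a fixed seed", {
  mods <- make_model_rdms(12, seed = 81)
  cfg <- synthetic_config(n_objects = 12, n_subjects = 2, grid_dims = c(8, 8, 8),
                          seed = 82, regions = default_regimes(c(8, 8, 8), 3))
  s1 <- simulate_patterns(mods$V, mods$C, cfg)
  s2 <- simulate_patterns(mods$V, mods$C, cfg)
  expect_identical(s1$patterns$s01$visual$data, s2$patterns$s01$visual$data)
  expect_identical(
    as.data.frame(simulate_ratings(mods$V, noise_sd = 0.3, seed = 83)),
    as.data.frame(simulate_ratings(mods$V, noise_sd = 0.3, seed = 83)))
  expect_identical(
    as.data.frame(simulate_norms(mods$C, seed = 84)),
    as.data.frame(simulate_norms(mods$C, seed = 84)))
  expect_identical(simulate_embeddings(mods$C, mods$V, seed = 85),
                   simulate_embeddings(mods$C, mods$V, seed = 85))
})
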