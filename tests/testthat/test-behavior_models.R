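# Behavior-based models: rater screening, visual RDM, feature filtering,
# conceptual and embedding RDMs.

make_ratings <- function(pairs, likert_by_rater, catch = NULL) {
  rows <- list()
  for (r in names(likert_by_rater)) {
    lik <- likert_by_rater[[r]]
    rows[[r]] <- data.frame(rater = r, concept_a = pairs[, 1],
                            concept_b = pairs[, 2], likert = lik,
                            is_catch = FALSE, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, c(rows, list(catch)))
  rating_table(df$rater, df$concept_a, df$concept_b, df$likert, df$is_catch)
}

test_that("filter_raters drops exactly the raters failing a catch trial", {
  pairs <- cbind(c("a", "a", "b"), c("b", "c", "c"))
  catch <- data.frame(rater = c(rep("r1", 4), rep("r2", 4)),
                      concept_a = "a", concept_b = "a",
                      likert = c(5, 5, 5, 5, 5, 3, 5, 5),
                      is_catch = TRUE, stringsAsFactors = FALSE)
  rt <- make_ratings(pairs, list(r1 = c(5, 1, 2), r2 = c(4, 2, 3),
                                 r3 = c(3, 3, 3)), catch)
  out <- filter_raters(rt)
  expect_setequal(unique(out$rater), c("r1", "r3"))         # r2 failed one catch
  expect_identical(attr(out, "excluded_raters"), "r2")
  expect_identical(attr(out, "no_catch_raters"), "r3")      # retained, logged
  # retained records unchanged
  expect_identical(out[out$rater == "r1" & !out$is_catch, "likert"],
                   c(5L, 1L, 2L))
  # table without catch records is returned identically
  rt2 <- make_ratings(pairs, list(r1 = c(5, 1, 2)))
  expect_equal(as.data.frame(filter_raters(rt2)), as.data.frame(rt2),
               ignore_attr = TRUE)
  expect_error(filter_raters(rt[0, ]), "no ratings")
})

test_that("visual_rdm hits the min-max endpoints", {
  # every rater rates pair (a,b) 5 and every other pair 1
  pairs <- cbind(c("a", "a", "b"), c("b", "c", "c"))
  rt <- make_ratings(pairs, list(r1 = c(5, 1, 1), r2 = c(5, 1, 1)))
  v <- visual_rdm(rt)
  expect_equal(unclass(v)["a", "b"], 0)
  expect_equal(unclass(v)["a", "c"], 1)
  expect_equal(unclass(v)["b", "c"], 1)
  expect_identical(rdm_measure(v), "one_minus_normalized_rating")
})

test_that("visual_rdm matches a spreadsheet-style min-max oracle", {
  # 4 concepts, hand-set pair means {ab,ac,ad,bc,bd,cd} = {2,3,4,2.5,3.5,3}
  pairs <- rbind(c("a","b"), c("a","c"), c("a","d"),
                 c("b","c"), c("b","d"), c("c","d"))
  rt <- make_ratings(pairs, list(r1 = c(2, 3, 4, 2, 3, 3),
                                 r2 = c(2, 3, 4, 3, 4, 3)))
  means <- c(2, 3, 4, 2.5, 3.5, 3)
  oracle <- 1 - (means - min(means)) / (max(means) - min(means))
  v <- visual_rdm(rt)
  got <- unclass(v)[cbind(pairs[, 1], pairs[, 2])]
  expect_equal(got, oracle)
  # invariant to record order and duplication of a complete rater block
  shuf <- rt[rev(seq_len(nrow(rt))), ]
  class(shuf) <- class(rt)
  expect_equal(unclass(visual_rdm(shuf)), unclass(v))
  dup <- rbind(as.data.frame(rt), as.data.frame(rt))
  dup$rater <- c(rt$rater, paste0(rt$rater, "bis"))
  dup <- rating_table(dup$rater, dup$concept_a, dup$concept_b, dup$likert, dup$is_catch)
  expect_equal(unclass(visual_rdm(dup)), unclass(v))
})

test_that("visual_rdm rejects degenerate and incomplete inputs", {
  pairs <- cbind(c("a", "a", "b"), c("b", "c", "c"))
  flat <- make_ratings(pairs, list(r1 = c(3, 3, 3)))
  expect_error(visual_rdm(flat), "degenerate normalization")
  incomplete <- make_ratings(pairs[1:2, , drop = FALSE], list(r1 = c(1, 5)))
  expect_error(visual_rdm(incomplete), "missing ratings")
})

test_that("filter_features applies the reliability and tag rules", {
  norms <- feature_norms(
    concept = c("dog", "dog", "dog", "cat", "cat"),
    feature = c("barks", "is round", "has fur", "meows", "HAS   Fur"),
    producer_count = c(3, 10, 4, 7, 12),
    tags = c("none", "visual_form", "none", "none", "none"))
  m <- filter_features(norms, min_count = 4, exclude_tags = c("visual_form", "color"))
  expect_setequal(colnames(m), c("has fur", "meows"))     # canonicalized merge
  expect_equal(m["dog", "has fur"], 4)                    # boundary 4/20 retained
  expect_false("barks" %in% colnames(m))                  # 3/20 dropped
  expect_false("is round" %in% colnames(m))               # visual_form dropped
  # min_count = 1, no exclusions reproduces the full matrix
  m0 <- filter_features(norms, min_count = 1, exclude_tags = character(0))
  expect_equal(sum(m0), sum(norms$producer_count))
  # a concept losing all features is an error naming it
  lonely <- feature_norms(c("dog", "axe"), c("barks", "is sharp"), c(10, 2))
  expect_error(filter_features(lonely, 4), "axe")
})

test_that("conceptual_rdm is 1 - cosine of count vectors", {
  m <- matrix(c(3, 0, 1, 2,
                3, 0, 1, 2,
                0, 5, 0, 0), 3, 4, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), paste0("f", 1:4)))
  r <- conceptual_rdm(m)
  expect_equal(unclass(r)["a", "b"], 0)                  # identical vectors
  expect_equal(unclass(r)["a", "c"], 1)                  # disjoint features
  cos_oracle <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(unclass(r)[i, j], 1 - cos_oracle(m[i, ], m[j, ]), tolerance = 1e-12)
  # invariance: feature permutation and uniform count scaling
  expect_equal(unclass(conceptual_rdm(m[, c(3, 1, 4, 2)])), unclass(r))
  expect_equal(unclass(conceptual_rdm(m * 7)), unclass(r))
  expect_error(conceptual_rdm(rbind(m, z = c(0, 0, 0, 0))), "zero-norm")
})

test_that("embedding_rdm handles identity, orthogonality, and missing concepts", {
  e <- rbind(a = c(1, 0, 0), b = c(0, 1, 0), c = c(1, 0, 0))
  r <- embedding_rdm(e)
  expect_equal(unclass(r)["a", "c"], 0)
  expect_equal(unclass(r)["a", "b"], 1)
  expect_equal(diag(unclass(r)), c(a = 0, b = 0, c = 0))
  expect_error(embedding_rdm(e, concepts = c("a", "zebra")), "zebra")
})

test_that("produced RDMs satisfy the RDM invariants", {
  mods <- make_model_rdms(12, seed = 5)
  rt <- simulate_ratings(mods$V, noise_sd = 0.3, seed = 6)
  nm <- simulate_norms(mods$C, seed = 7)
  em <- simulate_embeddings(mods$C, mods$V, leak = 0.2, seed = 8)
  for (r in list(visual_rdm(filter_raters(rt)),
                 conceptual_rdm(filter_features(nm)),
                 embedding_rdm(em))) {
    m <- unclass(r)
    expect_equal(m, t(m))
    expect_identical(diag(m), setNames(rep(0, nrow(m)), rownames(m)))
    rng <- if (rdm_measure(r) == "one_minus_normalized_rating") c(0, 1) else c(0, 2)
    expect_true(all(m >= rng[1] - 1e-12 & m <= rng[2] + 1e-12))
  }
})
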