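# Second-level RSA statistics: tie-aware Kendall tau-a, stimulus-label
# randomization tests, one-sided Wilcoxon signed-rank, tau -> r -> Fisher-z
# transforms, 2x2 repeated-measures interaction, Bonferroni correction.

#' Kendall's tau-a rank correlation
#'
#' `tau_a = (C - D) / (m (m - 1) / 2)`: concordant minus discordant pairs over
#' all pairs. Pairs tied in either vector count as neither concordant nor
#' discordant, which makes tau-a the appropriate statistic for sparse model
#' RDMs predicting many tied dissimilarities (ties shrink tau-a toward zero
#' rather than being renormalized away as in tau-b).
#'
#' @param x,y numeric vectors of equal length (typically RDM lower triangles,
#'   see [rdm_vec()])
#' @return tau-a in \[-1, 1\]
#' @export
kendall_tau_a <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2) stop("need at least 2 values")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  .tau_a_cpp(as.numeric(x), as.numeric(y))
}

#' Stimulus-label randomization test for RDM relatedness
#'
#' Computes tau-a between the lower triangles of two RDMs and builds a null
#' distribution by repeatedly permuting the object labels of one RDM
#' (simultaneous row and column permutation) and recomputing tau-a, simulating
#' the null hypothesis of unrelated RDMs. One-sided upper-tail p with the +1
#' correction: `p = (1 + #{null >= observed}) / (1 + n_iter)`.
#'
#' @param a,b `rdm`s sharing condition labels (b is aligned to a's order)
#' @param n_iter number of label permutations (study value 10000)
#' @param seed RNG seed (restored on exit); NULL uses the current stream
#' @return list of class `model_comparison` with `tau_a`, `p`, `n_null`,
#'   `null_mean`, `null_sd`, `seed`
#' @export
randomization_test <- function(a, b, n_iter = 10000L, seed = NULL) {
  if (!setequal(rdm_labels(a), rdm_labels(b)))
    stop("RDMs do not share condition labels")
  n <- nrow(a)
  if (n < 4) stop("need at least 4 conditions")
  b <- rdm_align(b, rdm_labels(a))
  av <- rdm_vec(a)
  bm <- unclass(as.matrix(b))
  bv <- bm[lower.tri(bm)]
  if (min(av) == max(av) || min(bv) == max(bv))
    stop("tau undefined: constant lower triangle")
  obs <- .tau_a_cpp(av, bv)
  null <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      p <- sample.int(n)
      pm <- bm[p, p]
      .tau_a_cpp(av, pm[lower.tri(pm)])
    }, numeric(1))
  })
  structure(list(tau_a = obs,
                 p = (1 + sum(null >= obs)) / (1 + n_iter),
                 n_null = n_iter, null_mean = mean(null), null_sd = sd(null),
                 seed = seed),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Kendall tau-a = %.4f, randomization p = %.4g (n_null = %d, null sd = %.4f)\n",
              x$tau_a, x$p, x$n_null, x$null_sd))
  invisible(x)
}

#' One-sided Wilcoxon signed-rank test (median > 0)
#'
#' Zeros are dropped before ranking (classic Wilcoxon handling). For n <= 25
#' the exact null distribution of W+ is computed by generating-function
#' convolution over the (possibly tied, average) ranks, which is valid with
#' ties; for larger n a normal approximation with tie and continuity
#' correction is used.
#'
#' @param values numeric vector, n >= 5 after zero removal
#' @return one-sided upper-tail p-value, with attributes `statistic` (W+) and
#'   `n` (nonzero count)
#' @export
wilcoxon_signed_rank_one_sided <- function(values) {
  if (any(!is.finite(values))) stop("non-finite values")
  v <- values[values != 0]
  if (length(values) > 0 && length(v) == 0) stop("all values are zero")
  n <- length(v)
  if (n < 5) stop("need at least 5 nonzero values")
  rk <- rank(abs(v))
  W <- sum(rk[v > 0])
  if (n <= 25) {
    # exact null of W+ via the generating function prod_i (1 + z^{r_i}) / 2^n,
    # on doubled ranks so tied (half-integer) average ranks become integers
    r2 <- as.integer(round(2 * rk))
    f <- c(1, rep(0, sum(r2)))
    for (r in r2) {
      shifted <- c(rep(0, r), f[seq_len(length(f) - r)])
      f <- f + shifted
    }
    w_vals <- seq_along(f) - 1L
    p <- sum(f[w_vals >= round(2 * W) - 1e-9]) / 2^n
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(rk)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    p <- pnorm((W - mu - 0.5) / sqrt(sigma2), lower.tail = FALSE)
  }
  structure(p, statistic = W, n = n)
}

#' Map Kendall's tau to Pearson's r
#'
#' Greiner's relation for bivariate normal ranks: `r = sin(pi/2 * tau)`. Used
#' before Fisher-z transformation and parametric group statistics on tau-a
#' coefficients.
#'
#' @param tau tau value(s) in \[-1, 1\]
#' @return r value(s)
#' @export
tau_to_r <- function(tau) {
  if (any(abs(tau) > 1, na.rm = TRUE)) stop("|tau| must be <= 1")
  sin(pi / 2 * tau)
}

#' Fisher z-transform of a correlation
#'
#' @param r correlation(s), |r| < 1
#' @return `atanh(r)`
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) stop("|r| must be < 1 (infinite z)")
  atanh(r)
}

#' 2x2 repeated-measures ANOVA interaction
#'
#' For a complete two-by-two within-subject design (here: behavior-based model
#' {visual, conceptual} crossed with task context {visual, conceptual}), the
#' interaction F with df (1, n-1) equals the squared paired t-statistic of the
#' per-subject difference of differences
#' `(m1c1 - m2c1) - (m1c2 - m2c2)`.
#'
#' @param table subjects x 4 numeric matrix, columns ordered
#'   (model1/ctx1, model2/ctx1, model1/ctx2, model2/ctx2)
#' @return list with `F`, `df` (length 2), `p`
#' @export
rm_anova_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (ncol(tab) != 4) stop("table must have 4 condition columns")
  if (any(!is.finite(tab))) stop("missing or non-finite cells")
  n <- nrow(tab)
  if (n < 3) stop("need at least 3 subjects")
  d <- (tab[, 1] - tab[, 2]) - (tab[, 3] - tab[, 4])
  eps <- 1e-10 * max(abs(tab), 1)
  if (sd(d) <= eps) {
    # additive (or constant-interaction) table up to rounding noise
    Fval <- if (abs(mean(d)) <= eps) 0 else Inf
  } else {
    Fval <- (mean(d) / (sd(d) / sqrt(n)))^2
  }
  list(F = Fval, df = c(1L, n - 1L), p = pf(Fval, 1, n - 1, lower.tail = FALSE))
}

#' Bonferroni adjustment
#'
#' @param p_values p-values in \[0, 1\]
#' @param m number of comparisons (may exceed `length(p_values)`)
#' @return adjusted p-values `min(1, p * m)`
#' @seealso [bonferroni_alpha()] for the corresponding critical alpha
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (m < 1) stop("m must be >= 1")
  if (m < length(p_values)) stop("m must be >= length(p_values)")
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  pmin(1, p_values * m)
}

#' Bonferroni critical alpha
#' @param m number of comparisons
#' @param alpha familywise alpha (default 0.05)
#' @return `alpha / m`
#' @export
bonferroni_alpha <- function(m, alpha = 0.05) {
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

#' Group-level model fit across subjects
#'
#' Per-subject tau-a between each subject RDM and a model RDM, the group mean,
#' a one-sided Wilcoxon signed-rank p (median tau > 0 across subjects as a
#' random factor), and a Bonferroni-adjusted significance flag.
#'
#' @param subject_rdms list of subject `rdm`s sharing labels with `model`
#' @param model model `rdm`
#' @param m number of comparisons for Bonferroni (default 1)
#' @param alpha familywise alpha (default 0.05)
#' @return list of class `group_model_fit` with `tau` (per subject),
#'   `mean_tau`, `p`, `p_adj`, `significant`
#' @export
group_model_fit <- function(subject_rdms, model, m = 1L, alpha = 0.05) {
  mv <- rdm_vec(model)
  tau <- vapply(subject_rdms, function(s) {
    s <- rdm_align(s, rdm_labels(model))
    kendall_tau_a(rdm_vec(s), mv)
  }, numeric(1))
  p <- as.numeric(wilcoxon_signed_rank_one_sided(tau))
  p_adj <- bonferroni(p, m)
  structure(list(tau = tau, mean_tau = mean(tau), p = p, p_adj = p_adj,
                 significant = p < bonferroni_alpha(m, alpha)),
            class = "group_model_fit")
}

#' @export
print.group_model_fit <- function(x, ...) {
  cat(sprintf("group model fit: mean tau-a = %.4f over %d subjects, Wilcoxon p = %.4g (adj %.4g)%s\n",
              x$mean_tau, length(x$tau), x$p, x$p_adj,
              if (x$significant) " *" else ""))
  invisible(x)
}
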