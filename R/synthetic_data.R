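# Synthetic-data generators: every input the pipeline consumes, with known
# representational structure. Two near-orthogonal model RDMs (visual V and
# conceptual C) are built by a chained-pair design; multi-voxel patterns are
# drawn from object covariances that mix the two model similarity structures
# with region- and context-specific weights; ratings, feature norms, embedding
# vectors and BOLD series are derived from the same ground truth.

#' Synthetic-study configuration
#'
#' Defaults mirror the study scale: 40 object concepts, 16 subjects, 8 runs,
#' 15 raters per pair, 20 feature producers. The voxel grid defaults to
#' 12 x 12 x 12 with four cubic regions implementing the four regional coding
#' regimes (see [default_regimes()]).
#'
#' @param n_objects number of object concepts (default 40)
#' @param n_subjects number of subjects (default 16)
#' @param n_runs runs per context (default 8)
#' @param grid_dims voxel grid dimensions (default c(12, 12, 12))
#' @param regions regime map, see [default_regimes()]
#' @param noise_sd per-run voxel noise sd relative to unit pattern variance
#' @param rating_noise_sd sd of rater noise on the latent similarity scale
#' @param n_raters raters per pair (default 15)
#' @param n_producers feature-norm producers (default 20)
#' @param seed master seed
#' @return list of class `synthetic_config`
#' @export
synthetic_config <- function(n_objects = 40L, n_subjects = 16L, n_runs = 8L,
                             grid_dims = c(12L, 12L, 12L),
                             regions = default_regimes(grid_dims),
                             noise_sd = 1, rating_noise_sd = 0.25,
                             n_raters = 15L, n_producers = 20L, seed = 1L) {
  stopifnot(n_objects >= 8, n_objects %% 2 == 0, n_subjects >= 1, n_runs >= 1,
            noise_sd >= 0, n_raters >= 1, n_producers >= 1)
  for (rg in regions) {
    for (w in rg$weights) {
      if (any(w < 0) || sum(w) > 1)
        stop("regime weights must be nonnegative with w_visual + w_conceptual <= 1")
    }
  }
  structure(list(n_objects = n_objects, n_subjects = n_subjects,
                 n_runs = n_runs, grid_dims = grid_dims, regions = regions,
                 noise_sd = noise_sd, rating_noise_sd = rating_noise_sd,
                 n_raters = n_raters, n_producers = n_producers, seed = seed),
            class = "synthetic_config")
}

#' Default regional coding regimes
#'
#' Four well-separated cubic regions on the grid, emulating the four ROI
#' coding profiles under study:
#' \describe{
#'   \item{loc_like}{visual code, visual task context only (task-dependent)}
#'   \item{phc_like}{conceptual code, conceptual task context only
#'     (task-dependent)}
#'   \item{tp_like}{conceptual code in both contexts (task-invariant)}
#'   \item{prc_like}{both visual and conceptual codes in both contexts
#'     (integrative)}
#' }
#' Weights are `(w_visual, w_conceptual)` mixture loadings per context;
#' background voxels outside all regions carry no model structure.
#'
#' @param grid_dims voxel grid dimensions (each >= 8)
#' @param side cube side length (default 4)
#' @return named list of regions, each `list(lo, hi, weights)`
#' @export
default_regimes <- function(grid_dims, side = 4L) {
  stopifnot(all(grid_dims >= 2 * side))
  g <- grid_dims
  cube <- function(lo) list(lo = lo, hi = lo + side - 1L)
  corners <- list(c(1L, 1L, 1L), c(g[1] - side + 1L, 1L, 1L),
                  c(1L, g[2] - side + 1L, 1L),
                  c(g[1] - side + 1L, g[2] - side + 1L, 1L))
  list(
    loc_like = c(cube(corners[[1]]),
                 list(weights = list(visual = c(0.5, 0), conceptual = c(0, 0)))),
    phc_like = c(cube(corners[[2]]),
                 list(weights = list(visual = c(0, 0), conceptual = c(0, 0.5)))),
    tp_like  = c(cube(corners[[3]]),
                 list(weights = list(visual = c(0, 0.5), conceptual = c(0, 0.5)))),
    prc_like = c(cube(corners[[4]]),
                 list(weights = list(visual = c(0.35, 0.35),
                                     conceptual = c(0.35, 0.35)))))
}

#' Chained-pair model RDMs with near-orthogonal structure
#'
#' Builds a visual RDM V and a conceptual RDM C over the same objects: in V,
#' objects (1,2), (3,4), ... are similar pairs; in C the chain is shifted by
#' one, (2,3), (4,5), ..., (n,1), so every object has one visually similar
#' partner and one different conceptually similar partner (visually similar
#' pairs are conceptually distinct and vice versa). Partner dissimilarities
#' are drawn low (0.05-0.2) and background dissimilarities high with jitter
#' (0.4-1.0); draws are repeated until |tau-a(V, C)| < `tol`.
#'
#' @param n_objects even number >= 8
#' @param tol orthogonality tolerance on tau-a (default 0.02)
#' @param seed RNG seed
#' @param max_tries maximum redraws before giving up
#' @return list with `V`, `C` (both `rdm`), `tau` (achieved tau-a)
#' @export
make_model_rdms <- function(n_objects = 40L, tol = 0.02, seed = NULL,
                            max_tries = 100L) {
  stopifnot(n_objects >= 8, n_objects %% 2 == 0)
  labels <- sprintf("obj%02d", seq_len(n_objects))
  v_pairs <- cbind(seq(1, n_objects - 1, by = 2), seq(2, n_objects, by = 2))
  c_pairs <- cbind(seq(2, n_objects, by = 2),
                   c(seq(3, n_objects - 1, by = 2), 1L))
  draw <- function(pairs) {
    n <- n_objects
    d <- matrix(0, n, n)
    bg <- runif(n * (n - 1) / 2, 0.4, 1.0)
    d[lower.tri(d)] <- bg
    d <- d + t(d)
    lo <- runif(nrow(pairs), 0.05, 0.2)
    d[pairs] <- lo; d[pairs[, c(2, 1)]] <- lo
    diag(d) <- 0
    d
  }
  with_seed(seed, {
    best_tau <- Inf
    for (i in seq_len(max_tries)) {
      dv <- draw(v_pairs); dc <- draw(c_pairs)
      tau <- .tau_a_cpp(dv[lower.tri(dv)], dc[lower.tri(dc)])
      if (abs(tau) < abs(best_tau)) best_tau <- tau
      if (abs(tau) < tol) {
        V <- rdm(dv, labels, measure = "other", note = "synthetic visual model")
        C <- rdm(dc, labels, measure = "other", note = "synthetic conceptual model")
        return(list(V = V, C = C, tau = tau))
      }
    }
    stop(sprintf("orthogonality tolerance %.3g unreachable in %d tries; best tau %.4f",
                 tol, max_tries, best_tau))
  })
}

# Project a symmetric unit-diagonal similarity matrix into the PSD cone by a
# spectral shift: S' = (S + lambda I) / (1 + lambda) with lambda just above
# -min(eigenvalue). Unlike eigenvalue clipping, the shift keeps the diagonal
# at 1 and rescales all off-diagonals by a common factor, so the off-diagonal
# rank order of the target similarity is preserved exactly — which is what
# makes the generated patterns recover the model RDM's rank structure at the
# noise-free ceiling. Returns the projected matrix and a factor L with
# S' = L %*% t(L).
psd_project <- function(S, eps = 1e-10) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  mn <- min(e$values)
  if (mn < eps) {
    lam <- -mn + eps + 1e-8
    vals <- (e$values + lam) / (1 + lam)
  } else {
    vals <- e$values
  }
  if (min(vals) < 0) stop("covariance not positive semi-definite after projection")
  L <- e$vectors %*% diag(sqrt(vals), length(vals))
  list(S = L %*% t(L), L = L)
}

#' Simulate multi-subject whole-volume patterns from model RDMs
#'
#' For each region with context weights `(wv, wc)`, the object-by-object
#' target similarity is `wv (1 - V) + wc (1 - C) + (1 - wv - wc) I`, projected
#' to the nearest positive semi-definite matrix and used as the covariance of
#' per-voxel object response profiles. The visual and conceptual pattern
#' components are drawn once per subject and shared across contexts, so a
#' region loading on the same component in both contexts represents objects
#' task-invariantly (high within-object cross-context similarity), while the
#' residual component is context-specific. Run-level Gaussian noise of sd
#' `noise_sd` is added; the returned pattern sets are run averages (noise sd
#' `noise_sd / sqrt(n_runs)`).
#'
#' @param V,C model `rdm`s from [make_model_rdms()]
#' @param config a `synthetic_config`
#' @return list with `patterns` (`patterns[[subject]][[context]]`, each a
#'   whole-volume `pattern_set` with voxels in mask order), `truth` (ground
#'   truth: V, C, regimes, per-region voxel positions), `mask` (logical
#'   `volume`), `voxel_index`
#' @export
simulate_patterns <- function(V, C, config) {
  n <- config$n_objects
  stopifnot(nrow(V) == n, nrow(C) == n)
  dims <- config$grid_dims
  mask <- array(TRUE, dims)
  nvox <- prod(dims)
  lin <- function(lo, hi) {
    idx <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
    sort(idx[, 1] + dims[1] * (idx[, 2] - 1) + dims[1] * dims[2] * (idx[, 3] - 1))
  }
  region_vox <- lapply(config$regions, function(r) lin(r$lo, r$hi))
  if (anyDuplicated(unlist(region_vox))) stop("regions overlap")
  Lv <- psd_project(1 - unclass(as.matrix(V)))$L
  Lc <- psd_project(1 - unclass(as.matrix(C)))$L
  run_sd <- config$noise_sd / sqrt(config$n_runs)
  contexts <- c("visual", "conceptual")
  labels <- rdm_labels(V)
  with_seed(config$seed, {
    subj <- vector("list", config$n_subjects)
    names(subj) <- sprintf("s%02d", seq_len(config$n_subjects))
    for (s in seq_len(config$n_subjects)) {
      base <- list()
      for (rg in names(config$regions)) {
        k <- length(region_vox[[rg]])
        base[[rg]] <- list(
          zv = Lv %*% matrix(rnorm(n * k), n, k),
          zc = Lc %*% matrix(rnorm(n * k), n, k))
      }
      ctx_sets <- list()
      for (ctx in contexts) {
        P <- matrix(rnorm(n * nvox), n, nvox)      # unique/noise component, sd 1
        for (rg in names(config$regions)) {
          w <- config$regions[[rg]]$weights[[ctx]]
          vx <- region_vox[[rg]]
          P[, vx] <- sqrt(w[1]) * base[[rg]]$zv +
            sqrt(w[2]) * base[[rg]]$zc +
            sqrt(max(0, 1 - w[1] - w[2])) * P[, vx, drop = FALSE]
        }
        P <- P + matrix(rnorm(n * nvox, sd = run_sd), n, nvox)
        rownames(P) <- labels
        ctx_sets[[ctx]] <- pattern_set(P, subject = names(subj)[s],
                                       context = ctx, roi = "whole_volume")
      }
      subj[[s]] <- ctx_sets
    }
    truth <- list(V = V, C = C, regimes = config$regions,
                  region_voxels = region_vox)
    list(patterns = subj, truth = truth,
         mask = volume(mask), voxel_index = which(mask))
  })
}

#' Extract a region-of-interest pattern set from a whole-volume simulation
#'
#' @param sim result of [simulate_patterns()]
#' @param subject subject id (name in `sim$patterns`)
#' @param context `"visual"` or `"conceptual"`
#' @param region region name in the regime map
#' @return a `pattern_set` restricted to the region's voxels
#' @export
roi_patterns <- function(sim, subject, context, region) {
  ps <- sim$patterns[[subject]][[context]]
  vx <- match(sim$truth$region_voxels[[region]], sim$voxel_index)
  pattern_set(ps$data[, vx, drop = FALSE], subject = subject,
              context = context, roi = region)
}

#' Simulate pairwise visual-similarity ratings
#'
#' Each rater rates every unordered pair on the 5-point Likert scale. The
#' latent rating is `1 + 4 (1 - V_ij)` plus a deterministic rater-specific
#' criterion offset (raters differ in where they place their category
#' boundaries; offsets span one scale step, which dithers the rounding so the
#' across-rater mean is a fine-grained monotone readout of the latent
#' similarity) plus optional Gaussian noise. Each rater also receives
#' `n_catch` identical-pair catch trials; a `fail_fraction` of raters rate one
#' catch trial 3 ("neutral") and should be excluded by [filter_raters()].
#'
#' @param V visual model `rdm`
#' @param n_raters raters per pair (default 15)
#' @param noise_sd rater noise on the latent scale (default 0)
#' @param fail_fraction fraction of raters failing one catch trial
#' @param n_catch catch trials per rater (default 4)
#' @param seed RNG seed
#' @return a `rating_table`
#' @export
simulate_ratings <- function(V, n_raters = 15L, noise_sd = 0,
                             fail_fraction = 0, n_catch = 4L, seed = NULL) {
  labels <- rdm_labels(V)
  m <- unclass(as.matrix(V))
  lt <- which(lower.tri(m), arr.ind = TRUE)
  latent <- 1 + 4 * (1 - m[lower.tri(m)])
  offs <- (seq_len(n_raters) - (n_raters + 1) / 2) / n_raters
  n_fail <- floor(fail_fraction * n_raters)
  with_seed(seed, {
    recs <- vector("list", n_raters)
    for (r in seq_len(n_raters)) {
      lik <- clamp(round(latent + offs[r] +
                           if (noise_sd > 0) rnorm(length(latent), sd = noise_sd) else 0),
                   1, 5)
      catch_concepts <- sample(labels, n_catch)
      catch_lik <- rep(5L, n_catch)
      if (r <= n_fail) catch_lik[1] <- 3L
      recs[[r]] <- data.frame(
        rater = sprintf("r%02d", r),
        concept_a = c(labels[lt[, 1]], catch_concepts),
        concept_b = c(labels[lt[, 2]], catch_concepts),
        likert = c(as.integer(lik), catch_lik),
        is_catch = c(rep(FALSE, length(latent)), rep(TRUE, n_catch)),
        stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, recs)
    rating_table(df$rater, df$concept_a, df$concept_b, df$likert, df$is_catch)
  })
}

#' Simulate conceptual feature-generation norms
#'
#' Builds a feature assignment whose concept-pair cosine structure matches
#' `1 - C` in rank order. Pairwise similarities are scaled so each concept's
#' total shared feature mass fits its norm budget, then each pairwise dot
#' product is realized as shared features with integer production counts in
#' 4..n_producers (greedy sum-of-squares decomposition); unique filler
#' features equalize concept norms. Decoy features exercise the filtering
#' rules: visual-form/color-tagged features shared by random concept triples,
#' and unreliable features with counts below 4.
#'
#' @param C conceptual model `rdm`
#' @param n_producers producers (default 20; also the maximum count)
#' @param target_norm2 squared feature-count norm per concept (default 40000)
#' @param n_tagged number of visual_form/color decoy features (default
#'   `nrow(C)`)
#' @param n_unreliable low-count decoy features per concept (default 2)
#' @param seed RNG seed
#' @return a `feature_norms` table
#' @export
simulate_norms <- function(C, n_producers = 20L, target_norm2 = 40000,
                           n_tagged = nrow(C), n_unreliable = 2L, seed = NULL) {
  labels <- rdm_labels(C)
  n <- length(labels)
  s <- 1 - unclass(as.matrix(C)); diag(s) <- 0
  scale <- 0.9 / max(rowSums(s))
  d_target <- s * scale * target_norm2
  cmax <- n_producers
  acc <- new.env(parent = emptyenv())
  acc$concept <- character(0); acc$feature <- character(0)
  acc$count <- integer(0); acc$tags <- character(0)
  add <- function(concept, feature, count, tags = "none") {
    acc$concept <- c(acc$concept, concept)
    acc$feature <- c(acc$feature, feature)
    acc$count <- c(acc$count, as.integer(count))
    acc$tags <- c(acc$tags, tags)
  }
  shared2 <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    rem <- d_target[i, j]
    k <- 0L
    while (rem >= 16) {
      cc <- min(cmax, floor(sqrt(rem)))
      k <- k + 1L
      f <- sprintf("shared %03d %03d %d", i, j, k)
      add(labels[i], f, cc)
      add(labels[j], f, cc)
      shared2[i, j] <- shared2[i, j] + cc^2
      rem <- rem - cc^2
    }
  }
  shared_mass <- rowSums(shared2 + t(shared2))
  for (i in seq_len(n)) {
    u <- target_norm2 - shared_mass[i]
    k <- 0L
    while (u >= 16) {
      cc <- min(cmax, floor(sqrt(u)))
      k <- k + 1L
      add(labels[i], sprintf("unique %03d %d", i, k), cc)
      u <- u - cc^2
    }
  }
  with_seed(seed, {
    for (t in seq_len(n_tagged)) {
      tag <- if (t %% 2 == 0) "visual_form" else "color"
      who <- sample(labels, 3)
      for (w in who)
        add(w, sprintf("%s decoy %03d", tag, t), sample(4:cmax, 1), tag)
    }
    for (i in seq_len(n)) for (k in seq_len(n_unreliable))
      add(labels[i], sprintf("unreliable %03d %d", i, k), sample(1:3, 1))
    feature_norms(acc$concept, acc$feature, acc$count,
                  n_producers = n_producers, tags = acc$tags)
  })
}

#' Simulate word-embedding vectors
#'
#' Produces vectors whose pairwise cosine similarity approximates
#' `(1 - leak) (1 - C) + leak (1 - V)`: with `leak = 0` the embedding carries
#' pure conceptual structure, while positive leak mixes in visual structure
#' (emulating corpus-based embeddings capturing visual semantics too). The
#' target Gram matrix is PSD-projected, factored, row-normalized, and
#' embedded in `dim` dimensions by a random rotation.
#'
#' @param C,V model `rdm`s
#' @param leak visual-structure leak in \[0, 1\] (default 0)
#' @param dim embedding dimension (default 300)
#' @param seed RNG seed
#' @return numeric matrix, one unit-norm row per concept
#' @export
simulate_embeddings <- function(C, V, leak = 0, dim = 300L, seed = NULL) {
  stopifnot(leak >= 0, leak <= 1)
  labels <- rdm_labels(C)
  n <- length(labels)
  if (dim < n) stop("embedding dimension must be >= number of concepts")
  G <- (1 - leak) * (1 - unclass(as.matrix(C))) + leak * (1 - unclass(as.matrix(V)))
  diag(G) <- 1
  X <- psd_project(G)$L                        # n x n factor
  nrm <- sqrt(rowSums(X^2))
  X <- X / nrm
  with_seed(seed, {
    Q <- qr.Q(qr(matrix(rnorm(dim * n), dim, n)))  # dim x n orthonormal
    E <- X %*% t(Q)
    rownames(E) <- labels
    colnames(E) <- sprintf("d%03d", seq_len(dim))
    E
  })
}

#' Simulate an event-related BOLD time series
#'
#' `y = design(events) %*% amplitudes + drift + noise`, returning the series
#' together with the generating amplitudes.
#'
#' @param events single-run `event_table`
#' @param amplitudes objects x voxels matrix (or named vector for one voxel)
#'   of response amplitudes
#' @param noise_sd Gaussian noise sd (>= 0)
#' @param tr repetition time (default 2)
#' @param n_volumes volumes in the run
#' @param drift_slope optional linear drift per volume (default 0)
#' @param seed RNG seed
#' @return list with `ts` (a `timeseries`), `amplitudes`, `design`
#' @export
simulate_bold <- function(events, amplitudes, noise_sd, tr = 2, n_volumes,
                          drift_slope = 0, seed = NULL) {
  if (noise_sd < 0) stop("noise sd must be nonnegative")
  X <- build_design(events, tr, n_volumes)
  objects <- setdiff(colnames(X), "(intercept)")
  A <- if (is.matrix(amplitudes)) amplitudes else
    matrix(amplitudes, ncol = 1, dimnames = list(names(amplitudes), "v1"))
  if (!all(objects %in% rownames(A))) stop("amplitudes missing for some objects")
  y0 <- X[, objects, drop = FALSE] %*% A[objects, , drop = FALSE]
  drift <- drift_slope * (seq_len(n_volumes) - 1)
  with_seed(seed, {
    y <- y0 + drift + matrix(rnorm(length(y0), sd = noise_sd),
                             nrow(y0), ncol(y0))
    list(ts = timeseries(y, tr = tr, run = events$run[1]),
         amplitudes = A[objects, , drop = FALSE], design = X)
  })
}
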