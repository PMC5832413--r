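# Readers/writers: labeled RDM CSV matrices (supplementary source-data
# layout), long-format rating/norms/embedding TSVs, plain-text volume maps,
# and recomputation of the printed statistics from a deposited source-data
# directory.

#' Write an RDM as a labeled CSV matrix
#'
#' Concept labels in the first row and column, dissimilarities in the body.
#'
#' @param x an `rdm`
#' @param path output file
#' @export
write_rdm_csv <- function(x, path) {
  m <- as.matrix(unclass(x))
  df <- data.frame(concept = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an RDM from a labeled CSV matrix
#'
#' Loads a square labeled matrix. If `similarity` is TRUE, or is NA (the
#' default) and the diagonal is detected to be 1 (a similarity matrix stores
#' self-similarity 1), values are converted by `1 - value`. Asymmetry beyond
#' 1e-6 and a nonzero diagonal after conversion are errors.
#'
#' @param path CSV file: first column concept labels, remaining columns the
#'   matrix
#' @param similarity TRUE, FALSE, or NA for diagonal auto-detection
#' @param measure measure tag for the resulting `rdm`
#' @return an `rdm`
#' @export
read_rdm_csv <- function(path, similarity = NA,
                         measure = c("other", "one_minus_pearson",
                                     "one_minus_cosine",
                                     "one_minus_normalized_rating")) {
  measure <- match.arg(measure)
  df <- read.table(path, sep = ",", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  labels <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m)) stop("matrix is not square")
  rownames(m) <- labels
  if (max(abs(m - t(m))) > 1e-6) stop("matrix asymmetric beyond tolerance 1e-6")
  if (is.na(similarity)) similarity <- all(abs(diag(m) - 1) < 1e-6)
  if (similarity) m <- 1 - m
  if (max(abs(diag(m))) > 1e-6)
    stop("nonzero diagonal after conversion; wrong similarity flag?")
  diag(m) <- 0
  rdm(m, labels = labels, measure = measure, note = paste("read from", basename(path)),
      tol = 1e-6)
}

#' Write / read long-format tables as TSV
#'
#' Rating tables, feature norms, event tables and subject-statistic tables are
#' serialized as plain TSV with a header row.
#'
#' @param x data.frame
#' @param path file path
#' @export
write_tsv <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Read a rating table TSV
#' @param path TSV with columns rater, concept_a, concept_b, likert, is_catch
#' @return a `rating_table`
#' @export
read_ratings_tsv <- function(path) {
  df <- read_tsv(path)
  rating_table(df$rater, df$concept_a, df$concept_b, df$likert,
               as.logical(df$is_catch))
}

#' Read a feature-norms TSV
#' @param path TSV with columns concept, feature, producer_count, n_producers,
#'   tags
#' @return a `feature_norms`
#' @export
read_norms_tsv <- function(path) {
  df <- read_tsv(path)
  feature_norms(df$concept, df$feature, df$producer_count,
                n_producers = df$n_producers[1] %||% 20L, tags = df$tags)
}

#' Read an embedding-vector TSV
#' @param path TSV: first column concept, remaining columns vector components
#' @return numeric matrix with concept rownames
#' @export
read_embeddings_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write / read a volume as a plain-text voxel table
#'
#' Text stand-in for NIfTI (no NIfTI reader is available in the target R
#' stack): a TSV of (i, j, k, value) for nonzero/non-NA voxels plus a JSON
#' sidecar holding dims and affine.
#'
#' @param x a `volume`
#' @param path TSV path; the sidecar is `path` with extension `.json`
#' @export
write_volume_tsv <- function(x, path) {
  arr <- as.array(x)
  keep <- which(!is.na(arr) & arr != 0, arr.ind = TRUE)
  df <- data.frame(i = keep[, 1], j = keep[, 2], k = keep[, 3],
                   value = as.numeric(arr[keep]))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(dims = dim(arr), affine = vol_affine(x),
         type = if (is.logical(arr)) "logical" else "numeric",
         fill = if (is.logical(arr)) FALSE else 0),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_volume_tsv
#' @return for `read_volume_tsv`, a `volume`
#' @export
read_volume_tsv <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dims <- as.integer(hdr$dims)
  fill <- if (identical(hdr$type, "logical")) FALSE else 0
  arr <- array(fill, dims)
  df <- read_tsv(path)
  if (nrow(df) > 0)
    arr[cbind(df$i, df$j, df$k)] <-
      if (identical(hdr$type, "logical")) as.logical(df$value) else df$value
  volume(arr, matrix(as.numeric(hdr$affine), 4, 4, byrow = FALSE))
}

#' Recompute the printed statistics from a deposited source-data directory
#'
#' Given a directory holding the deposited supplementary files in the layout
#' below, recomputes every published behavior-level statistic with the
#' package's own routines:
#' \itemize{
#'   \item `visual_rdm.csv`, `conceptual_rdm.csv`, `word2vec_rdm.csv`:
#'     labeled 40 x 40 matrices (similarity or dissimilarity, auto-detected) —
#'     model-to-model tau-a values and the gun-hairdryer cells.
#'   \item `roi_model_tau.tsv`: participant rows; columns
#'     `<roi>_<context>_<model>` tau-a coefficients — group means and the
#'     2x2 interaction F after tau -> r -> Fisher-z.
#'   \item `cross_context_tau.tsv`: columns `<roi>` — cross-context RDM
#'     correlation group means.
#'   \item `within_object_r.tsv`: columns `<roi>` — within-object Pearson r
#'     group means.
#' }
#'
#' @param dir directory containing the files
#' @param n_iter randomization iterations for model-to-model p-values
#' @param seed RNG seed for the randomization tests
#' @return named list of recomputed statistics
#' @export
recompute_supplementary <- function(dir, n_iter = 10000L, seed = 1L) {
  pth <- function(f) file.path(dir, f)
  out <- list()
  vis <- read_rdm_csv(pth("visual_rdm.csv"))
  con <- read_rdm_csv(pth("conceptual_rdm.csv"))
  w2v <- read_rdm_csv(pth("word2vec_rdm.csv"))
  out$tau_visual_conceptual <- kendall_tau_a(rdm_vec(vis), rdm_vec(rdm_align(con, rdm_labels(vis))))
  out$tau_w2v_conceptual <- kendall_tau_a(rdm_vec(w2v), rdm_vec(rdm_align(con, rdm_labels(w2v))))
  out$tau_w2v_visual <- kendall_tau_a(rdm_vec(w2v), rdm_vec(rdm_align(vis, rdm_labels(w2v))))
  out$p_visual_conceptual <- randomization_test(vis, con, n_iter, seed)$p
  gh <- function(r) unclass(r)["gun", "hairdryer"]
  out$gun_hairdryer_w2v_cosine <- 1 - gh(w2v)
  out$gun_hairdryer_conceptual_cosine <- 1 - gh(con)
  out$gun_hairdryer_visual_rating <- 1 - gh(vis)
  if (file.exists(pth("roi_model_tau.tsv"))) {
    tab <- read_tsv(pth("roi_model_tau.tsv"))
    out$group_means <- colMeans(tab)
    prc_cols <- c("prc_visual_visual", "prc_visual_conceptual",
                  "prc_conceptual_visual", "prc_conceptual_conceptual")
    if (all(prc_cols %in% names(tab))) {
      z <- fisher_z(tau_to_r(as.matrix(tab[prc_cols])))
      out$prc_interaction <- rm_anova_2x2(z)
    }
  }
  if (file.exists(pth("cross_context_tau.tsv")))
    out$cross_context_means <- colMeans(read_tsv(pth("cross_context_tau.tsv")))
  if (file.exists(pth("within_object_r.tsv")))
    out$within_object_means <- colMeans(read_tsv(pth("within_object_r.tsv")))
  out$bonferroni_alpha_16 <- bonferroni_alpha(16)
  out
}
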