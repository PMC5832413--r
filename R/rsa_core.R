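# First-level RSA: correlation-distance RDMs from pattern sets, and
# within-object similarity of the same object's patterns across task contexts.

#' Brain-based RDM from a pattern set
#'
#' Cell (i, j) is the correlation distance `1 - Pearson's r` between the
#' voxel vectors of objects i and j. Pearson correlation is computed across
#' voxels within the ROI/mask, with no additional pattern normalization.
#'
#' @param patterns a `pattern_set` with at least two voxels
#' @return an `rdm` with measure `one_minus_pearson`; subject, context and ROI
#'   carried in attributes `subject`, `context`, `roi`
#' @export
pattern_rdm <- function(patterns) {
  x <- patterns$data
  if (ncol(x) < 2) stop("need at least 2 voxels")
  v <- apply(x, 1, sd)
  if (any(v == 0))
    stop("zero-variance pattern for object(s): ",
         paste(rownames(x)[v == 0], collapse = ", "))
  d <- 1 - cor(t(x))
  out <- rdm(d, labels = rownames(x), measure = "one_minus_pearson",
             note = sprintf("first-level RSA: subject %s, context %s, roi %s",
                            patterns$subject, patterns$context, patterns$roi))
  attr(out, "subject") <- patterns$subject
  attr(out, "context") <- patterns$context
  attr(out, "roi") <- patterns$roi
  out
}

#' Within-object pattern similarity across task contexts
#'
#' For each object, the Pearson correlation between its mean multi-voxel
#' pattern in one task context and in the other. High values mean the region
#' represents an object the same way regardless of task; values near zero mean
#' context-dependent coding. Reported as similarity r (the corresponding
#' dissimilarity is 1 - r).
#'
#' @param a,b `pattern_set`s for the same subject/ROI in two different task
#'   contexts, sharing object labels and voxel space
#' @return list of class `within_object_result` with per-object `r`, `mean_r`,
#'   `subject`, `roi`
#' @export
within_object_similarity <- function(a, b) {
  if (!identical(sort(rownames(a$data)), sort(rownames(b$data))))
    stop("object label mismatch between pattern sets")
  if (identical(a$context, b$context))
    stop("pattern sets must come from different task contexts")
  if (ncol(a$data) != ncol(b$data)) stop("voxel spaces differ")
  bb <- b$data[rownames(a$data), , drop = FALSE]
  r <- vapply(seq_len(nrow(a$data)),
              function(i) cor(a$data[i, ], bb[i, ]), numeric(1))
  names(r) <- rownames(a$data)
  structure(list(r = r, mean_r = mean(r), subject = a$subject, roi = a$roi),
            class = "within_object_result")
}
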