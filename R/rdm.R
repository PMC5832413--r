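#' Representational dissimilarity matrix (RDM)
#'
#' An RDM is a square symmetric matrix of pairwise dissimilarities between
#' labeled conditions (here, object concepts), with an exactly zero diagonal.
#' Each RDM carries a `measure` tag recording the dissimilarity it holds:
#' \describe{
#'   \item{one_minus_normalized_rating}{1 - min-max-normalized mean similarity
#'     rating; values in \[0, 1\].}
#'   \item{one_minus_cosine}{1 - cosine similarity of nonnegative feature or
#'     embedding vectors; values in \[0, 1\] for nonnegative vectors.}
#'   \item{one_minus_pearson}{correlation distance between multi-voxel
#'     patterns; values in \[0, 2\].}
#' }
#'
#' @param mat square numeric matrix of dissimilarities
#' @param labels character vector of condition labels; defaults to
#'   `rownames(mat)`
#' @param measure dissimilarity measure tag (see Details)
#' @param note free-text provenance note
#' @param tol symmetry tolerance
#' @return an object of class `rdm` (a classed matrix)
#' @export
rdm <- function(mat,
                labels = rownames(mat),
                measure = c("one_minus_pearson", "one_minus_cosine",
                            "one_minus_normalized_rating", "other"),
                note = "", tol = 1e-8) {
  measure <- match.arg(measure)
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("RDM must be square")
  if (is.null(labels)) labels <- paste0("obj", seq_len(nrow(mat)))
  if (length(labels) != nrow(mat)) stop("label length mismatch")
  if (anyDuplicated(labels)) stop("duplicate condition labels")
  if (any(!is.finite(mat))) stop("RDM contains non-finite values")
  if (max(abs(mat - t(mat))) > tol) stop("RDM not symmetric within tolerance")
  if (max(abs(diag(mat))) > tol) stop("RDM diagonal not zero within tolerance")
  mat <- (mat + t(mat)) / 2
  diag(mat) <- 0
  # one_minus_cosine admits [0,2]: signed embedding vectors can anti-correlate;
  # nonnegative count vectors stay in [0,1] but that is a property, not a bound.
  rng <- switch(measure,
    one_minus_normalized_rating = c(0 - tol, 1 + tol),
    one_minus_cosine            = c(0 - tol, 2 + tol),
    one_minus_pearson           = c(0 - tol, 2 + tol),
    other                       = c(-Inf, Inf))
  if (any(mat < rng[1]) || any(mat > rng[2]))
    stop("RDM values outside range for measure ", measure)
  dimnames(mat) <- list(labels, labels)
  structure(mat, class = c("rdm", "matrix", "array"),
            measure = measure, note = note)
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("RDM: %d x %d conditions, measure = %s\n",
              nrow(x), ncol(x), attr(x, "measure")))
  if (nzchar(attr(x, "note") %||% "")) cat("note:", attr(x, "note"), "\n")
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))), drop = FALSE])
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Test whether an object is an RDM
#' @param x object
#' @return logical
#' @export
is_rdm <- function(x) inherits(x, "rdm")

#' Condition labels of an RDM
#' @param x an `rdm`
#' @return character vector
#' @export
rdm_labels <- function(x) rownames(x)

#' Dissimilarity measure tag of an RDM
#' @param x an `rdm`
#' @return character scalar
#' @export
rdm_measure <- function(x) attr(x, "measure")

#' Lower-triangle vector of an RDM
#'
#' Extracts the below-diagonal dissimilarities in column-major order, the fixed
#' pair order used throughout for rank comparison of RDMs. Pair labels are
#' attached as names ("a|b").
#'
#' @param x an `rdm` or square symmetric matrix
#' @return numeric vector of length n(n-1)/2
#' @export
rdm_vec <- function(x) {
  m <- as.matrix(x)
  lt <- lower.tri(m)
  v <- m[lt]
  lab <- rownames(m) %||% as.character(seq_len(nrow(m)))
  names(v) <- paste(lab[row(m)[lt]], lab[col(m)[lt]], sep = "|")
  v
}

#' Build an RDM as 1 - similarity
#'
#' @param sim square symmetric similarity matrix with labels
#' @param measure RDM measure tag for the result
#' @param note provenance note
#' @return an `rdm`
#' @keywords internal
rdm_from_similarity <- function(sim, measure, note = "") {
  d <- 1 - sim
  diag(d) <- 0
  rdm(d, labels = rownames(sim), measure = measure, note = note)
}

#' Align an RDM to a given label order
#' @param x an `rdm`
#' @param labels character vector, a permutation of `rdm_labels(x)`
#' @return the reordered `rdm`
#' @export
rdm_align <- function(x, labels) {
  if (!setequal(labels, rdm_labels(x)) || length(labels) != nrow(x))
    stop("labels are not a permutation of the RDM's labels")
  rdm(unclass(x)[labels, labels], labels = labels,
      measure = rdm_measure(x), note = attr(x, "note") %||% "")
}
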