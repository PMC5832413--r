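# Behavior-based similarity models: visual RDM from pairwise Likert ratings,
# conceptual RDM from feature-generation norms, embedding RDM from word vectors.

#' Construct a rating table
#'
#' Long-format table of pairwise visual-similarity ratings on a 5-point Likert
#' scale (1 = very dissimilar ... 5 = very similar). Catch trials pair a
#' concept with itself and are used to screen inattentive raters.
#'
#' @param rater rater ids
#' @param concept_a,concept_b concept labels of the rated pair
#' @param likert integer ratings in 1..5
#' @param is_catch logical; must equal `concept_a == concept_b`
#' @return a `data.frame` of class `rating_table`
#' @export
rating_table <- function(rater, concept_a, concept_b, likert, is_catch) {
  df <- data.frame(rater = as.character(rater),
                   concept_a = as.character(concept_a),
                   concept_b = as.character(concept_b),
                   likert = as.integer(likert),
                   is_catch = as.logical(is_catch),
                   stringsAsFactors = FALSE)
  if (any(!df$likert %in% 1:5)) stop("likert ratings must be in 1..5")
  if (any(df$is_catch != (df$concept_a == df$concept_b)))
    stop("is_catch must flag exactly the self-pairs")
  class(df) <- c("rating_table", "data.frame")
  df
}

#' Exclude raters who fail catch trials
#'
#' Removes every record of any rater who rated a catch trial (identical-pair
#' trial) below `min_catch_likert`. The default 4 corresponds to "somewhat
#' similar": attentive raters should judge an object as at least somewhat
#' similar to itself. Raters without catch records are retained and listed in
#' the `no_catch_raters` attribute.
#'
#' @param ratings a `rating_table`
#' @param min_catch_likert minimum acceptable catch-trial rating (default 4)
#' @return the filtered `rating_table`, with attributes `excluded_raters` and
#'   `no_catch_raters`
#' @export
filter_raters <- function(ratings, min_catch_likert = 4L) {
  if (nrow(ratings) == 0) stop("no ratings")
  catch <- ratings[ratings$is_catch, , drop = FALSE]
  bad <- unique(catch$rater[catch$likert < min_catch_likert])
  no_catch <- setdiff(unique(ratings$rater), unique(catch$rater))
  out <- ratings[!ratings$rater %in% bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded_raters") <- bad
  attr(out, "no_catch_raters") <- no_catch
  class(out) <- c("rating_table", "data.frame")
  out
}

# Canonical unordered-pair key: lexicographically smaller label first.
pair_key <- function(a, b) {
  lo <- ifelse(a <= b, a, b)
  hi <- ifelse(a <= b, b, a)
  list(lo = lo, hi = hi, key = paste(lo, hi, sep = "\r"))
}

#' Behavior-based visual RDM from similarity ratings
#'
#' Averages Likert ratings per unordered concept pair, min-max normalizes the
#' pair means to \[0, 1\], and stores 1 - normalized mean as the dissimilarity.
#' Catch (self-pair) records are ignored; the table should already be
#' rater-filtered (see [filter_raters()]).
#'
#' @param ratings a `rating_table` covering every unordered pair of its
#'   concepts at least once
#' @return an `rdm` with measure `one_minus_normalized_rating`
#' @export
visual_rdm <- function(ratings) {
  r <- ratings[!ratings$is_catch, , drop = FALSE]
  if (nrow(r) == 0) stop("no ratings")
  pk <- pair_key(r$concept_a, r$concept_b)
  concepts <- sort(unique(c(r$concept_a, r$concept_b)))
  n <- length(concepts)
  means <- tapply(r$likert, pk$key, mean)
  want <- outer(concepts, concepts, function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r"))
  want_keys <- want[lower.tri(want)]
  missing <- setdiff(want_keys, names(means))
  if (length(missing) > 0)
    stop("missing ratings for ", length(missing), " pair(s), e.g. ",
         gsub("\r", "-", missing[1]))
  mn <- min(means); mx <- max(means)
  if (mx == mn) stop("degenerate normalization: all pair means identical")
  normed <- (means - mn) / (mx - mn)
  d <- matrix(0, n, n, dimnames = list(concepts, concepts))
  d[lower.tri(d)] <- 1 - normed[want_keys]
  d <- d + t(d)
  rdm(d, labels = concepts, measure = "one_minus_normalized_rating",
      note = "visual similarity ratings, 1 - min-max normalized pair mean")
}

#' Construct a feature-norms table
#'
#' Long-format conceptual feature-generation norms: each row records that
#' `producer_count` of `n_producers` participants listed `feature` for
#' `concept`. Feature strings are canonicalized (case-folded, trimmed,
#' internal whitespace collapsed). `tags` marks features describing visual
#' form or color so they can be excluded from the conceptual model.
#'
#' @param concept concept labels
#' @param feature feature strings
#' @param producer_count integer counts in 1..n_producers
#' @param n_producers total producers per concept (study value 20)
#' @param tags character; comma-separated subset of
#'   `{visual_form, color}` or `"none"`
#' @return a `data.frame` of class `feature_norms`
#' @export
feature_norms <- function(concept, feature, producer_count,
                          n_producers = 20L, tags = "none") {
  feat <- canonicalize_feature(feature)
  df <- data.frame(concept = as.character(concept), feature = feat,
                   producer_count = as.integer(producer_count),
                   n_producers = as.integer(n_producers),
                   tags = as.character(tags), stringsAsFactors = FALSE)
  if (any(df$producer_count < 1L) || any(df$producer_count > df$n_producers))
    stop("producer_count must lie in 1..n_producers")
  if (anyDuplicated(df[c("concept", "feature")]))
    stop("duplicate (concept, feature) entries after canonicalization")
  class(df) <- c("feature_norms", "data.frame")
  df
}

canonicalize_feature <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

#' Filter feature norms and build the concept-by-feature count matrix
#'
#' Applies the reliability rule (drop entries produced by fewer than
#' `min_count` of the producers; study rule: fewer than 4 of 20) and removes
#' features tagged with any tag in `exclude_tags` (study: visual-form and
#' color features, so the conceptual model holds only abstract conceptual
#' properties).
#'
#' @param norms a `feature_norms` table
#' @param min_count minimum producer count to retain an entry (default 4)
#' @param exclude_tags tags whose features are dropped entirely
#'   (default `c("visual_form", "color")`)
#' @return concepts x features integer matrix of production counts, class
#'   `concept_feature_matrix`
#' @export
filter_features <- function(norms, min_count = 4L,
                            exclude_tags = c("visual_form", "color")) {
  if (min_count < 1L) stop("min_count must be >= 1")
  concepts <- sort(unique(norms$concept))
  tag_list <- strsplit(norms$tags, ",[[:space:]]*")
  tagged_out <- vapply(tag_list, function(t) any(t %in% exclude_tags), logical(1))
  keep <- norms$producer_count >= min_count & !tagged_out
  kept <- norms[keep, , drop = FALSE]
  empty <- setdiff(concepts, unique(kept$concept))
  if (length(empty) > 0)
    stop("concept(s) with zero surviving features: ",
         paste(empty, collapse = ", "))
  feats <- sort(unique(kept$feature))
  m <- matrix(0L, length(concepts), length(feats),
              dimnames = list(concepts, feats))
  m[cbind(match(kept$concept, concepts), match(kept$feature, feats))] <-
    kept$producer_count
  class(m) <- c("concept_feature_matrix", "matrix", "array")
  m
}

#' Behavior-based conceptual RDM from a concept-feature count matrix
#'
#' Dissimilarity is 1 - cosine similarity between the production-count vectors
#' of two concepts. Counts are used as-is (feature frequencies), not
#' binarized, so features listed by more producers weigh more.
#'
#' @param mat a `concept_feature_matrix` (concepts x features counts)
#' @return an `rdm` with measure `one_minus_cosine`
#' @export
conceptual_rdm <- function(mat) {
  m <- unclass(as.matrix(mat))
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("negative production counts")
  s <- cosine_rows(m)
  rdm_from_similarity(s, "one_minus_cosine",
                      note = "conceptual feature norms, 1 - cosine of count vectors")
}

#' Embedding-based RDM from a word-vector table
#'
#' Dissimilarity is 1 - cosine similarity between the fixed-length embedding
#' vectors (word2vec-style) of two concepts.
#'
#' @param table numeric matrix with one row per concept (rownames are concept
#'   labels), or a `data.frame` in the same layout
#' @param concepts concept labels to extract, in RDM order
#' @return an `rdm` with measure `one_minus_cosine`
#' @export
embedding_rdm <- function(table, concepts = rownames(table)) {
  x <- as.matrix(table)
  storage.mode(x) <- "double"
  miss <- setdiff(concepts, rownames(x))
  if (length(miss) > 0)
    stop("concept(s) missing from embedding table: ", paste(miss, collapse = ", "))
  x <- x[concepts, , drop = FALSE]
  s <- cosine_rows(x)
  rdm_from_similarity(pmin(s, 1), "one_minus_cosine",
                      note = "word embedding vectors, 1 - cosine")
}
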