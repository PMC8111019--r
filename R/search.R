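#' Build a searchable archive index
#'
#' Wraps a code/feature store as the search archive. Retrieval is an exact
#' exhaustive Euclidean scan (the reference implementation; no approximate
#' structure is used), so results are deterministic with ties broken by
#' archive insertion order.
#'
#' @param store a non-empty [feature_store()].
#' @return an object of class `archive_index`.
#' @export
build_index <- function(store) {
  stopifnot(inherits(store, "feature_store"))
  if (nrow(store$features) < 1L)
    stop("cannot index an empty store", call. = FALSE)
  structure(list(codes = store$features, ids = store$ids,
                 labels = store$labels, n = nrow(store$features),
                 dim = ncol(store$features),
                 # cached squared row norms for the batch distance kernel
                 sq_norms = rowSums(store$features^2)),
            class = "archive_index")
}

#' @export
print.archive_index <- function(x, ...) {
  cat(sprintf("<archive_index> n=%d, dim=%d\n", x$n, x$dim))
  invisible(x)
}

#' Retrieve the k nearest archived items for one query
#'
#' Exact Euclidean k-nearest-neighbour retrieval: distances to every
#' archived item are computed and the `k` smallest returned in ascending
#' order. Exact distance ties are broken by archive insertion order. If
#' `k` exceeds the archive size, all items are returned and the result is
#' flagged as truncated.
#'
#' @param index an [build_index()] archive.
#' @param query numeric vector of the archive's dimensionality.
#' @param k number of neighbours to retrieve (>= 1).
#' @param query_id optional id recorded in the result.
#' @return an object of class `retrieval_set`: list with `query_id`, `k`
#'   (requested), `ids`, `distances` (non-decreasing), `labels`, `m` (count
#'   of positive labels among the hits) and `truncated`.
#' @export
#' @examples
#' st <- feature_store(matrix(c(0, 0, 1, 0, 0, 2), 3, 2, byrow = TRUE),
#'                     ids = c("a", "b", "c"), labels = c(0, 1, 0))
#' knn(build_index(st), c(0, 0), k = 2)
knn <- function(index, query, k, query_id = NA_character_) {
  stopifnot(inherits(index, "archive_index"))
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  query <- as.numeric(query)
  if (length(query) != index$dim)
    stop(sprintf("query dim %d does not match index dim %d",
                 length(query), index$dim), call. = FALSE)
  d2 <- index$sq_norms - 2 * as.vector(index$codes %*% query) +
    sum(query^2)
  d2[d2 < 0] <- 0
  truncated <- k > index$n
  k_eff <- min(as.integer(k), index$n)
  ord <- order(d2)[seq_len(k_eff)]  # radix order: stable on ties
  labels <- index$labels[ord]
  structure(list(query_id = query_id, k = as.integer(k),
                 ids = index$ids[ord], distances = sqrt(d2[ord]),
                 labels = labels, m = sum(labels == 1L, na.rm = TRUE),
                 truncated = truncated),
            class = "retrieval_set")
}

#' @export
print.retrieval_set <- function(x, ...) {
  cat(sprintf("<retrieval_set> query=%s, %d hits (m=%d)%s\n", x$query_id,
              length(x$ids), x$m, if (x$truncated) " [truncated]" else ""))
  invisible(x)
}

# Batch kernel used by the CV harness: full query x archive squared
# Euclidean distance matrix via the expansion ||q||^2 + ||a||^2 - 2 q.a.
.distance_matrix <- function(queries, index) {
  d2 <- matrix(rowSums(queries^2), nrow(queries), index$n) +
    matrix(index$sq_norms, nrow(queries), index$n, byrow = TRUE) -
    2 * tcrossprod(queries, index$codes)
  d2[d2 < 0] <- 0
  d2
}

#' Majority-vote class likelihood of a retrieval
#'
#' The class likelihood of the query is the fraction `m / k` of positive
#' labels among the retrieved neighbours (using the effective retrieved
#' count when the request was clipped at the archive size).
#'
#' @param retrieval a [knn()] result with at least one hit.
#' @return real in `[0, 1]`.
#' @export
vote_likelihood <- function(retrieval) {
  stopifnot(inherits(retrieval, "retrieval_set"))
  n_hits <- length(retrieval$ids)
  if (n_hits < 1L) stop("empty retrieval", call. = FALSE)
  retrieval$m / n_hits
}

#' Threshold a vote likelihood into a class decision
#'
#' Positive if and only if `likelihood >= threshold` (so threshold 0
#' declares everything positive).
#'
#' @param likelihood vote likelihood(s) in `[0, 1]`.
#' @param threshold decision threshold in `[0, 1]`.
#' @return character vector, `"positive"` or `"negative"`.
#' @export
classify_likelihood <- function(likelihood, threshold) {
  if (any(likelihood < 0 | likelihood > 1) || threshold < 0 || threshold > 1)
    stop("likelihood and threshold must be in [0, 1]", call. = FALSE)
  ifelse(likelihood >= threshold, "positive", "negative")
}
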