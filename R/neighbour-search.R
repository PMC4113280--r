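#' One self-contained neighbour-search problem ("chunk")
#'
#' A chunk bundles a point cloud with the search parameters: every point is
#' both a search-space point and a reference point. Chunks are independent
#' by construction, which is what makes batches of original-plus-surrogate
#' search spaces trivially parallelisable.
#'
#' @param points numeric matrix `[n_points, dim]`, all finite.
#' @param k neighbour count for kNN searches (`n_points > k`).
#' @param rep,time optional integer origin tags per point (defaults give
#'   every point a distinct repetition, i.e. no Theiler exclusion).
#' @param theiler Theiler exclusion window in samples.
#' @param radii optional per-point radii; when present the chunk requests a
#'   strict range count instead of a kNN search.
#' @return An object of class `search_chunk`.
#' @export
search_chunk <- function(points, k = 4, rep = NULL, time = NULL,
                         theiler = 0, radii = NULL) {
  points <- as.matrix(points)
  if (!all(is.finite(points))) stop("chunk points must all be finite")
  n <- nrow(points)
  if (is.null(radii) && n <= k) stop("chunk needs n_points > k")
  if (is.null(rep)) rep <- seq_len(n)
  if (is.null(time)) time <- integer(n)
  if (length(rep) != n || length(time) != n)
    stop("origin tags must align with points")
  if (!is.null(radii) && length(radii) != n)
    stop("`radii` must align with points")
  structure(list(points = points, k = as.integer(k),
                 rep = as.integer(rep), time = as.integer(time),
                 theiler = as.integer(theiler), radii = radii),
            class = "search_chunk")
}

#' k-nearest-neighbour distances under the maximum norm
#'
#' For each point of the chunk, the max-norm distance to its k-th nearest
#' *other* point. The point itself and same-repetition points inside the
#' Theiler window are excluded. The `"oracle"` backend is an exhaustive
#' all-pairs scan; `"tree"` is a k-d tree with max-norm pruning. Both
#' return identical results.
#'
#' @param chunk a [search_chunk()].
#' @param backend `"tree"` or `"oracle"`.
#' @return Numeric vector of k-th neighbour distances.
#' @export
knn_search <- function(chunk, backend = c("tree", "oracle")) {
  stopifnot(inherits(chunk, "search_chunk"))
  backend <- match.arg(backend)
  cpp_knn_dist(chunk$points, chunk$k, chunk$rep, chunk$time, chunk$theiler,
               backend == "tree")
}

#' Strict-radius neighbour counts under the maximum norm
#'
#' Per point: the number of other points at max-norm distance *strictly*
#' less than its radius (KSG type-1 convention), under the same exclusion
#' rules as [knn_search()]. A radius of 0 therefore always counts 0.
#'
#' @param chunk a [search_chunk()].
#' @param radii per-point radii (defaults to `chunk$radii`).
#' @param backend `"tree"` or `"oracle"`.
#' @return Integer vector of counts.
#' @export
range_count <- function(chunk, radii = NULL, backend = c("tree", "oracle")) {
  stopifnot(inherits(chunk, "search_chunk"))
  backend <- match.arg(backend)
  if (is.null(radii)) radii <- chunk$radii
  if (is.null(radii)) stop("no radii supplied for range count")
  if (any(radii < 0)) stop("negative radius")
  cpp_range_count(chunk$points, as.numeric(radii), chunk$rep, chunk$time,
                  chunk$theiler, backend == "tree")
}

#' Execute a batch of independent search chunks
#'
#' Results are per-chunk and identical to sequential execution regardless
#' of batch composition or order — the parallel contract that allows an
#' original search space and all its surrogate search spaces to ride one
#' batch. A chunk whose search fails yields an element of class
#' `"search_error"` holding the message; the remaining chunks complete.
#'
#' @param chunks list of [search_chunk()] objects.
#' @param backend `"tree"` or `"oracle"`.
#' @return List of results: a numeric vector of k-th distances for kNN
#'   chunks, an integer vector of counts for range chunks.
#' @export
batched_search <- function(chunks, backend = c("tree", "oracle")) {
  backend <- match.arg(backend)
  lapply(chunks, function(ch) {
    tryCatch({
      if (!is.null(ch$radii)) range_count(ch, backend = backend)
      else knn_search(ch, backend = backend)
    }, error = function(e) structure(conditionMessage(e), class = "search_error"))
  })
}
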