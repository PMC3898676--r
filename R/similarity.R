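#' Parameters of the morphology similarity score
#'
#' @param sigma spatial scale of the score in um (> 0). Default 3 um, the
#'   scale of registration accuracy / biological variability in the fly
#'   brain template space.
#' @param symmetrize how to reconcile the asymmetric raw score when building
#'   a distance matrix: `"mean"` (default), `"min"`, `"max"` or `"none"`.
#' @return object of class `similarity_params`.
#' @export
similarity_params <- function(sigma = 3,
                              symmetrize = c("mean", "min", "max", "none")) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("sigma must be a single positive number")
  symmetrize <- match.arg(symmetrize)
  structure(list(sigma = sigma, symmetrize = symmetrize),
            class = "similarity_params")
}

# nearest neighbour of each query row in target: blocked exhaustive search.
# Ties broken to the lowest target index (which.min). Returns list(idx, d2).
nearest_neighbour <- function(query, target, block = 256L) {
  nq <- nrow(query)
  sq_t <- rowSums(target^2)
  idx <- integer(nq)
  d2 <- numeric(nq)
  for (start in seq(1L, nq, by = block)) {
    rows <- start:min(start + block - 1L, nq)
    qb <- query[rows, , drop = FALSE]
    dd <- outer(rowSums(qb^2), sq_t, "+") - 2 * tcrossprod(qb, target)
    j <- max.col(-dd, ties.method = "first")
    idx[rows] <- j
    d2[rows] <- dd[cbind(seq_along(rows), j)]
  }
  # the expanded form |q|^2+|t|^2-2qt leaves O(1e-9) cancellation error on
  # coincident points; snap to an exact zero well below the score's um scale
  d2[d2 < 1e-6] <- 0
  list(idx = idx, d2 = d2)
}

#' Morphology similarity score between two dot-property clouds
#'
#' For each point i of the query cloud, the nearest point j of the target
#' cloud is found (Euclidean); the pair contributes
#' `|q_i . t_j| * exp(-d_ij^2 / (2 sigma^2))`, the absolute dot product of
#' the two unit tangents weighted by a Gaussian in the point distance. The
#' score is the mean contribution over all query points: 1 for identical
#' neurons, 0 for completely different ones. The raw score is not symmetric
#' in query and target.
#'
#' @param query,target [dotprops()] objects.
#' @param params a [similarity_params()].
#' @return score in `[0, 1]`.
#' @export
similarity_score <- function(query, target, params = similarity_params()) {
  stopifnot(inherits(query, "dotprops"), inherits(target, "dotprops"),
            inherits(params, "similarity_params"))
  if (nzchar(query$space_tag) && nzchar(target$space_tag) &&
      !identical(query$space_tag, target$space_tag))
    warning("comparing dotprops from different registration spaces: '",
            query$space_tag, "' vs '", target$space_tag, "'")
  nn <- nearest_neighbour(query$points, target$points)
  dots <- abs(rowSums(query$tangents * target$tangents[nn$idx, , drop = FALSE]))
  # tangents are unit vectors, so |q.t| <= 1 up to fp error; clamp overshoot
  # and snap values a few ulp under 1 (self-matching tangents) to exactly 1
  dots[dots > 1 - 1e-12] <- 1
  mean(dots * exp(-nn$d2 / (2 * params$sigma^2)))
}

#' Pairwise distance matrix over a set of neurons
#'
#' Entry (a, b) is `1 - S(a, b)` (similarity converted to distance by
#' subtraction from 1), then symmetrized according to
#' `params$symmetrize` (default: mean of the two directed values).
#'
#' @param neurons named list of [dotprops()] (>= 2); unnamed entries are
#'   labelled by their `source_label`.
#' @param params a [similarity_params()].
#' @return object of class `distance_matrix`: list with `labels` and square
#'   numeric `values` in `[0, 1]`, zero diagonal.
#' @export
distance_matrix <- function(neurons, params = similarity_params()) {
  if (length(neurons) < 2L) stop("need at least 2 neurons")
  labels <- names(neurons)
  if (is.null(labels))
    labels <- vapply(neurons, function(d) d$source_label, character(1L))
  if (any(!nzchar(labels)) || anyDuplicated(labels))
    labels <- make.unique(ifelse(nzchar(labels), labels,
                                 paste0("neuron", seq_along(neurons))))
  n <- length(neurons)
  s <- matrix(0, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    s[a, b] <- if (a == b) 1 else
      similarity_score(neurons[[a]], neurons[[b]], params)
  }
  d <- 1 - s
  d <- switch(params$symmetrize,
              mean = (d + t(d)) / 2,
              min = pmin(d, t(d)),
              max = pmax(d, t(d)),
              none = d)
  d[d < 0] <- 0; d[d > 1] <- 1
  diag(d) <- 0
  dimnames(d) <- list(labels, labels)
  structure(list(labels = labels, values = d), class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> %d neurons; off-diagonal range [%.3f, %.3f]\n",
              length(x$labels), min(x$values[upper.tri(x$values)]),
              max(x$values[upper.tri(x$values)])))
  invisible(x)
}

#' Hierarchically cluster neurons from a distance matrix
#'
#' Agglomerative clustering of the morphology distances, by default with
#' classic Ward linkage on the unsquared distances (`stats::hclust`,
#' `method = "ward.D"`).
#'
#' @param dm a [distance_matrix()] (must be symmetric: symmetrize first).
#' @param method linkage passed to [stats::hclust()] (default `"ward.D"`).
#' @return an `hclust` merge tree.
#' @export
cluster_neurons <- function(dm, method = "ward.D") {
  stopifnot(inherits(dm, "distance_matrix"))
  if (max(abs(dm$values - t(dm$values))) > 1e-9)
    stop("distance matrix is asymmetric; rebuild with symmetrize != 'none'")
  stats::hclust(stats::as.dist(dm$values), method = method)
}

#' Cut a dendrogram into k groups
#'
#' @param tree an `hclust` tree from [cluster_neurons()].
#' @param k number of groups, `1 <= k <=` leaf count.
#' @return named integer vector of group labels in leaf input order.
#' @export
cut_clusters <- function(tree, k) {
  stopifnot(inherits(tree, "hclust"))
  n_leaves <- length(tree$order)
  if (k < 1L || k > n_leaves)
    stop("k must be between 1 and the leaf count (", n_leaves, ")")
  stats::cutree(tree, k = k)
}

#' Export a dendrogram as Newick
#'
#' Branch lengths derive from the merge heights (via [ape::as.phylo()]).
#' @param tree an `hclust` tree.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(tree, path) {
  stopifnot(inherits(tree, "hclust"))
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' Write a labelled distance matrix to CSV
#' @param dm a [distance_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path) {
  stopifnot(inherits(dm, "distance_matrix"))
  utils::write.csv(as.data.frame(dm$values), path, row.names = TRUE)
  invisible(path)
}
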