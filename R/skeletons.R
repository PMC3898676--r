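#' Construct a neuron skeleton
#'
#' A `neuron_skeleton` is a rooted tree (or forest) of 3D nodes in
#' micrometres, the unit of traced morphology. Coordinates are assumed to be
#' pre-registered to a common template space; `space_tag` records which one.
#'
#' @param nodes data.frame with columns `node_id` (integer, unique),
#'   `parent_id` (integer, `NA` for roots), `x`, `y`, `z` (um) and optionally
#'   `radius` (um).
#' @param label free-text neuron label.
#' @param space_tag free-text name of the registration space.
#' @return object of class `neuron_skeleton`.
#' @export
neuron_skeleton <- function(nodes, label = "", space_tag = "") {
  nodes <- as.data.frame(nodes)
  required <- c("node_id", "parent_id", "x", "y", "z")
  missing_cols <- setdiff(required, names(nodes))
  if (length(missing_cols) > 0L)
    stop("nodes is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!"radius" %in% names(nodes)) nodes$radius <- NA_real_
  nodes$node_id <- as.integer(nodes$node_id)
  nodes$parent_id <- as.integer(nodes$parent_id)
  skel <- structure(
    list(nodes = nodes[, c("node_id", "parent_id", "x", "y", "z", "radius")],
         label = as.character(label), space_tag = as.character(space_tag)),
    class = "neuron_skeleton")
  validate_skeleton(skel)
  skel
}

validate_skeleton <- function(skel) {
  nodes <- skel$nodes
  if (nrow(nodes) < 1L) stop("skeleton has no nodes")
  if (anyDuplicated(nodes$node_id))
    stop("node_ids are not unique")
  if (!all(is.finite(nodes$x) & is.finite(nodes$y) & is.finite(nodes$z)))
    stop("skeleton coordinates must all be finite")
  non_root <- !is.na(nodes$parent_id)
  dangling <- non_root & !(nodes$parent_id %in% nodes$node_id)
  if (any(dangling))
    stop("dangling parent reference for node(s) ",
         paste(nodes$node_id[dangling], collapse = ", "))
  # cycle check by pointer doubling: after ceil(log2(n)) squarings of the
  # parent map every node in a forest resolves to a root (NA); survivors
  # are on a cycle
  n <- nrow(nodes)
  anc <- match(nodes$parent_id, nodes$node_id)
  for (i in seq_len(ceiling(log2(max(n, 2))) + 1L)) anc <- anc[anc]
  if (any(!is.na(anc)))
    stop("cycle detected involving node(s) ",
         paste(utils::head(nodes$node_id[!is.na(anc)], 5L), collapse = ", "))
  invisible(skel)
}

#' @export
print.neuron_skeleton <- function(x, ...) {
  n_root <- sum(is.na(x$nodes$parent_id))
  cat(sprintf("<neuron_skeleton> '%s': %d nodes, %d root(s), cable %.1f um\n",
              x$label, nrow(x$nodes), n_root, total_cable_length(x)))
  invisible(x)
}

#' Read a neuron reconstruction from an SWC file
#'
#' Standard 7-column whitespace-separated SWC (`id type x y z radius parent`),
#' `#` comment lines, parent `-1` marking roots. Node order is preserved.
#'
#' @param path path to an SWC file.
#' @param label,space_tag metadata attached to the skeleton; `label` defaults
#'   to the file name.
#' @return a [neuron_skeleton()].
#' @export
read_swc <- function(path, label = NULL, space_tag = "") {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  line_no <- which(keep)
  rows <- strsplit(trimws(raw[keep]), "\\s+")
  bad <- which(lengths(rows) != 7L)
  if (length(bad) > 0L)
    stop("malformed SWC line ", line_no[bad[1L]], " in ", path,
         " (expected 7 fields, got ", lengths(rows)[bad[1L]], ")")
  m <- do.call(rbind, lapply(rows, as.numeric))
  if (anyNA(m)) {
    bad <- which(apply(m, 1L, anyNA))[1L]
    stop("malformed SWC line ", line_no[bad], " in ", path,
         " (non-numeric field)")
  }
  nodes <- data.frame(node_id = as.integer(m[, 1L]),
                      parent_id = as.integer(m[, 7L]),
                      x = m[, 3L], y = m[, 4L], z = m[, 5L],
                      radius = m[, 6L])
  nodes$parent_id[nodes$parent_id == -1L] <- NA_integer_
  neuron_skeleton(nodes, label = label %||% basename(path),
                  space_tag = space_tag)
}

#' Write a neuron skeleton to an SWC file
#'
#' Inverse of [read_swc()]: `read_swc(write_swc(s, f))` reproduces `s`'s node
#' table exactly.
#'
#' @param skel a [neuron_skeleton()].
#' @param path output path.
#' @param type SWC structure-type code written for every node (default 0,
#'   "undefined"; type codes are not modelled).
#' @return `path`, invisibly.
#' @export
write_swc <- function(skel, path, type = 0L) {
  validate_skeleton(skel)
  nodes <- skel$nodes
  radius <- ifelse(is.na(nodes$radius), 1, nodes$radius)
  parent <- ifelse(is.na(nodes$parent_id), -1L, nodes$parent_id)
  lines <- sprintf("%d %d %.17g %.17g %.17g %.17g %d",
                   nodes$node_id, type, nodes$x, nodes$y, nodes$z,
                   radius, parent)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# SWC exported by pherocircuit", lines), con)
  invisible(path)
}

edge_table <- function(skel) {
  nodes <- skel$nodes
  child <- which(!is.na(nodes$parent_id))
  parent_row <- match(nodes$parent_id[child], nodes$node_id)
  data.frame(child = child, parent = parent_row)
}

#' Total cable length of a skeleton
#'
#' Sum of Euclidean parent-child edge lengths, in micrometres.
#' @param skel a [neuron_skeleton()].
#' @return length in um.
#' @export
total_cable_length <- function(skel) {
  ed <- edge_table(skel)
  if (nrow(ed) == 0L) return(0)
  p <- as.matrix(skel$nodes[, c("x", "y", "z")])
  sum(sqrt(rowSums((p[ed$child, , drop = FALSE] -
                    p[ed$parent, , drop = FALSE])^2)))
}

#' Resample a skeleton to a maximum edge length
#'
#' Subdivides every parent-child edge longer than `step` into equal
#' collinear pieces, so that all edges are `<= step` um. Original nodes
#' (hence all branch and end points) are kept at their exact positions and
#' total cable length is conserved. Node ids are reassigned sequentially.
#'
#' @param skel a [neuron_skeleton()].
#' @param step maximum edge length in um (> 0). Default 1 um, well below the
#'   3 um spatial scale of the similarity score, so that scores are
#'   insensitive to the tracing's native node density.
#' @return a resampled [neuron_skeleton()].
#' @export
resample_skeleton <- function(skel, step = 1) {
  validate_skeleton(skel)
  if (!is.numeric(step) || length(step) != 1L || !is.finite(step) || step <= 0)
    stop("step must be a single positive number")
  nodes <- skel$nodes
  p <- as.matrix(nodes[, c("x", "y", "z")])
  ed <- edge_table(skel)

  new_id <- seq_len(nrow(nodes))          # originals keep their row order
  out_x <- nodes$x; out_y <- nodes$y; out_z <- nodes$z
  out_r <- nodes$radius
  out_parent <- rep(NA_integer_, nrow(nodes))
  out_parent[ed$child] <- ed$parent
  next_id <- nrow(nodes)

  add_x <- add_y <- add_z <- add_r <- numeric(0)
  add_parent <- integer(0)
  patch_child <- integer(0)   # original child rows to re-parent
  patch_to <- integer(0)

  for (e in seq_len(nrow(ed))) {
    a <- ed$parent[e]; b <- ed$child[e]
    seg <- p[b, ] - p[a, ]
    len <- sqrt(sum(seg^2))
    n_pieces <- ceiling(len / step)
    if (n_pieces <= 1L) next
    frac <- seq_len(n_pieces - 1L) / n_pieces
    ids <- next_id + seq_len(n_pieces - 1L)
    next_id <- next_id + n_pieces - 1L
    add_x <- c(add_x, p[a, 1L] + frac * seg[1L])
    add_y <- c(add_y, p[a, 2L] + frac * seg[2L])
    add_z <- c(add_z, p[a, 3L] + frac * seg[3L])
    add_r <- c(add_r, rep(NA_real_, n_pieces - 1L))
    add_parent <- c(add_parent, c(a, ids[-length(ids)]))
    patch_child <- c(patch_child, b)
    patch_to <- c(patch_to, ids[length(ids)])
  }

  out_parent[patch_child] <- patch_to
  all_parent <- c(out_parent, add_parent)
  new_nodes <- data.frame(
    node_id = seq_len(next_id),
    parent_id = all_parent,
    x = c(out_x, add_x), y = c(out_y, add_y), z = c(out_z, add_z),
    radius = c(out_r, add_r))
  neuron_skeleton(new_nodes, label = skel$label, space_tag = skel$space_tag)
}

#' Construct a dot-property point cloud
#'
#' The point-and-tangent (dot-property) representation of a neuron: an
#' unordered cloud of 3D positions with a unit tangent vector (local neurite
#' heading) at each point. This is the representation the similarity score
#' consumes.
#'
#' @param points N x 3 numeric matrix of positions (um).
#' @param tangents N x 3 numeric matrix of unit vectors.
#' @param source_label free-text provenance label.
#' @param space_tag registration-space tag carried from the skeleton.
#' @return object of class `dotprops`.
#' @export
dotprops <- function(points, tangents, source_label = "", space_tag = "") {
  points <- as.matrix(points); tangents <- as.matrix(tangents)
  storage.mode(points) <- "double"; storage.mode(tangents) <- "double"
  if (ncol(points) != 3L || ncol(tangents) != 3L)
    stop("points and tangents must have 3 columns")
  if (nrow(points) < 1L) stop("dotprops must contain at least one point")
  if (nrow(points) != nrow(tangents))
    stop("points and tangents must have the same number of rows")
  if (!all(is.finite(points)) || !all(is.finite(tangents)))
    stop("points and tangents must be finite")
  norms <- sqrt(rowSums(tangents^2))
  if (any(abs(norms - 1) > 1e-6))
    stop("tangents must be unit vectors (norm within 1e-6 of 1)")
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  dimnames(tangents) <- list(NULL, c("tx", "ty", "tz"))
  structure(list(points = points, tangents = tangents,
                 source_label = as.character(source_label),
                 space_tag = as.character(space_tag)),
            class = "dotprops")
}

#' @export
print.dotprops <- function(x, ...) {
  cat(sprintf("<dotprops> '%s': %d points\n", x$source_label,
              nrow(x$points)))
  invisible(x)
}

# first principal axis of a small point set, sign-normalized:
# nonnegative x, ties broken to nonnegative y then z
principal_axis <- function(pts) {
  cv <- stats::cov(pts)
  v <- eigen(cv, symmetric = TRUE)$vectors[, 1L]
  tol <- 1e-12
  flip <- if (abs(v[1L]) > tol) v[1L] < 0
          else if (abs(v[2L]) > tol) v[2L] < 0
          else v[3L] < 0
  if (flip) v <- -v
  v / sqrt(sum(v^2))
}

#' Convert a skeleton to its dot-property representation
#'
#' One point per node; the tangent at each point is the first principal axis
#' of the `k_neighbors` nearest nodes (including the point itself), estimated
#' by local PCA. The axis sign is normalized to nonnegative x (ties broken to
#' nonnegative y, then z), making the estimator deterministic and
#' rotation-equivariant up to sign.
#'
#' @param skel a [neuron_skeleton()].
#' @param k_neighbors neighbourhood size for the tangent PCA (>= 2,
#'   default 5).
#' @return a [dotprops()] object.
#' @export
to_dotprops <- function(skel, k_neighbors = 5L) {
  validate_skeleton(skel)
  k_neighbors <- as.integer(k_neighbors)
  if (k_neighbors < 2L) stop("k_neighbors must be >= 2")
  p <- as.matrix(skel$nodes[, c("x", "y", "z")])
  n <- nrow(p)
  if (n < k_neighbors)
    stop("skeleton has ", n, " nodes; k_neighbors = ", k_neighbors,
         " requires at least that many")
  nn_idx <- knn_indices(p, k_neighbors)
  tangents <- t(vapply(seq_len(n), function(i) {
    principal_axis(p[nn_idx[i, ], , drop = FALSE])
  }, numeric(3L)))
  dotprops(p, tangents, source_label = skel$label, space_tag = skel$space_tag)
}

# k nearest rows of p for every row of p (self included), by blocked
# exhaustive search; deterministic lowest-index tie-break via order()
knn_indices <- function(p, k, block = 512L) {
  n <- nrow(p)
  sq <- rowSums(p^2)
  out <- matrix(0L, n, k)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    # squared distances block x n
    d2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(p[idx, , drop = FALSE], p)
    for (r in seq_along(idx)) {
      out[idx[r], ] <- order(d2[r, ])[seq_len(k)]
    }
  }
  out
}

#' Write a dot-property cloud to CSV
#'
#' Columns `x,y,z,tx,ty,tz`; the inverse of [read_dotprops()].
#' @param dp a [dotprops()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dotprops <- function(dp, path) {
  stopifnot(inherits(dp, "dotprops"))
  utils::write.csv(cbind(as.data.frame(dp$points),
                         as.data.frame(dp$tangents)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a dot-property cloud from CSV
#' @param path CSV with columns `x,y,z,tx,ty,tz`.
#' @param source_label,space_tag metadata; `source_label` defaults to the
#'   file name.
#' @return a [dotprops()].
#' @export
read_dotprops <- function(path, source_label = NULL, space_tag = "") {
  df <- utils::read.csv(path)
  dotprops(df[, c("x", "y", "z")], df[, c("tx", "ty", "tz")],
           source_label = source_label %||% basename(path),
           space_tag = space_tag)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
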