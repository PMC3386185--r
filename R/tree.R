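#' Compartmentalized dendritic tree
#'
#' Construct a `dendrite_tree` from parent pointers.  A tree has exactly one
#' root (the soma), identified by a parent sentinel of `0`; every other
#' compartment points at its parent.  Indices are 1-based and contiguous.
#'
#' @param parent integer vector of length N; `parent[i]` is the index of the
#'   parent of compartment `i`, or `0` for the root.
#' @param xyz optional N x 3 numeric matrix of coordinates (micrometres).
#' @param radius optional numeric vector of compartment radii (micrometres).
#' @param edge_length optional numeric vector of distances to the parent
#'   (micrometres); computed from `xyz` when available, otherwise unit hops.
#'   The root entry is always 0.
#' @param type optional integer vector of SWC structure types.
#'
#' @return An object of class `dendrite_tree`: a list with elements
#'   `n`, `parent`, `xyz`, `radius`, `type`, `edge_length`, `topo_distance`
#'   (distance from the soma along the tree) and `depth` (hops from the soma).
#' @seealso [read_swc()], [prune_tree()], [directional_adjacency()]
#' @export
dendrite_tree <- function(parent, xyz = NULL, radius = NULL,
                          edge_length = NULL, type = NULL) {
  parent <- as.integer(parent)
  n <- length(parent)
  if (n < 1L) stop("tree must have at least one compartment")
  root <- which(parent == 0L)
  if (length(root) != 1L)
    stop("tree must have exactly one root (parent sentinel 0), found ",
         length(root))
  if (any(parent < 0L) || any(parent > n))
    stop("parent indices out of range")
  if (any(parent == seq_len(n)))
    stop("compartment cannot be its own parent")

  ord <- tree_order(parent, root)   # errors on cycles

  if (!is.null(xyz)) {
    xyz <- as.matrix(xyz)
    if (nrow(xyz) != n || ncol(xyz) != 3L)
      stop("xyz must be an N x 3 matrix")
  }
  if (is.null(edge_length)) {
    if (!is.null(xyz)) {
      edge_length <- numeric(n)
      nr <- seq_len(n)[-root]
      edge_length[nr] <- sqrt(rowSums((xyz[nr, , drop = FALSE] -
                                       xyz[parent[nr], , drop = FALSE])^2))
    } else {
      edge_length <- rep(1, n)
      edge_length[root] <- 0
    }
  }
  edge_length <- as.numeric(edge_length)
  if (length(edge_length) != n || any(edge_length < 0))
    stop("edge_length must be length N and nonnegative")
  edge_length[root] <- 0

  topo <- numeric(n)
  depth <- integer(n)
  for (i in ord[-1L]) {             # ord starts at root
    topo[i] <- topo[parent[i]] + edge_length[i]
    depth[i] <- depth[parent[i]] + 1L
  }

  structure(list(n = n, parent = parent, root = root, xyz = xyz,
                 radius = radius, type = type, edge_length = edge_length,
                 topo_distance = topo, depth = depth),
            class = "dendrite_tree")
}

# Topological order from root outwards; errors on cycles / unreachable nodes.
tree_order <- function(parent, root) {
  n <- length(parent)
  kids <- children_list(parent)
  ord <- integer(n)
  ord[1L] <- root
  head <- 1L; tail <- 1L
  while (head <= tail) {
    v <- ord[head]; head <- head + 1L
    for (k in kids[[v]]) {
      tail <- tail + 1L
      ord[tail] <- k
    }
  }
  if (tail != n)
    stop("parent pointers contain a cycle or disconnected compartments")
  ord
}

children_list <- function(parent) {
  n <- length(parent)
  kids <- vector("list", n)
  nz <- which(parent > 0L)
  if (length(nz)) {
    sp <- split(nz, parent[nz])
    kids[as.integer(names(sp))] <- sp
  }
  kids
}

#' Read an SWC morphology file
#'
#' Parses the standard 7-column SWC format (id, type, x, y, z, radius,
#' parent; `#` comments allowed).  Ids may be arbitrary but must be unique;
#' they are mapped to contiguous 1-based indices in file order.  Edge lengths
#' are Euclidean distances to the parent.
#'
#' @param path path to an SWC file.
#' @return A [dendrite_tree()].
#' @export
read_swc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no data rows in SWC file: ", path)
  fields <- strsplit(lines, "[[:space:]]+")
  if (any(lengths(fields) != 7L))
    stop("SWC rows must have 7 whitespace-separated columns")
  m <- suppressWarnings(
    matrix(as.numeric(unlist(fields)), ncol = 7L, byrow = TRUE))
  if (anyNA(m)) stop("non-numeric field in SWC file: ", path)
  ids <- as.integer(m[, 1L])
  if (anyDuplicated(ids)) stop("duplicate compartment ids in SWC file")
  par_id <- as.integer(m[, 7L])
  idx <- match(par_id, ids)            # NA for root (-1) or dangling
  parent <- ifelse(par_id == -1L, 0L, idx)
  if (anyNA(parent)) stop("SWC parent id not present in file")
  dendrite_tree(parent, xyz = m[, 3:5, drop = FALSE], radius = m[, 6L],
                type = as.integer(m[, 2L]))
}

#' Write a tree to an SWC file
#'
#' @param tree a [dendrite_tree()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(tree, path) {
  stopifnot(inherits(tree, "dendrite_tree"))
  xyz <- if (is.null(tree$xyz)) matrix(0, tree$n, 3L) else tree$xyz
  rad <- if (is.null(tree$radius)) rep(1, tree$n) else tree$radius
  typ <- if (is.null(tree$type)) c(1L, rep(3L, tree$n - 1L)) else tree$type
  par <- ifelse(tree$parent == 0L, -1L, tree$parent)
  df <- data.frame(seq_len(tree$n), typ, xyz[, 1L], xyz[, 2L], xyz[, 3L],
                   rad, par)
  utils::write.table(df, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Topological distances from the soma
#'
#' Distance from the root to every compartment measured along the tree
#' (not through space), in the units of `edge_length` (micrometres by
#' default, unit hops when `hops = TRUE`).
#'
#' @param tree a [dendrite_tree()].
#' @param hops if `TRUE`, count edges instead of summing edge lengths.
#' @return numeric vector of length N; the root entry is 0.
#' @export
topological_distances <- function(tree, hops = FALSE) {
  stopifnot(inherits(tree, "dendrite_tree"))
  if (hops) return(as.numeric(tree$depth))
  tree$topo_distance
}

#' Hop distances from a compartment
#'
#' Breadth-first distances (number of edges) from `from` to every
#' compartment, travelling along the undirected tree.
#'
#' @param tree a [dendrite_tree()].
#' @param from compartment index.
#' @param max_hops stop exploring beyond this many hops (remaining entries
#'   are `Inf`).
#' @return numeric vector of length N.
#' @export
hop_distances <- function(tree, from, max_hops = Inf) {
  stopifnot(inherits(tree, "dendrite_tree"),
            length(from) == 1L, from >= 1L, from <= tree$n)
  kids <- children_list(tree$parent)
  dist <- rep(Inf, tree$n)
  dist[from] <- 0
  frontier <- from
  h <- 0
  while (length(frontier) && h < max_hops) {
    h <- h + 1
    nxt <- integer(0)
    for (v in frontier) {
      nb <- c(kids[[v]], if (tree$parent[v] > 0L) tree$parent[v])
      nb <- nb[is.infinite(dist[nb])]
      dist[nb] <- h
      nxt <- c(nxt, nb)
    }
    frontier <- nxt
  }
  dist
}

#' Directional adjacency matrix
#'
#' Sparse N x N 0/1 matrix with entry (i, j) = 1 iff compartment i is the
#' parent of compartment j.  Each column has at most one nonzero; the root's
#' column is all zero; the total number of nonzeros is N - 1.
#'
#' @param tree a [dendrite_tree()].
#' @return a sparse `Matrix::sparseMatrix`.
#' @export
directional_adjacency <- function(tree) {
  stopifnot(inherits(tree, "dendrite_tree"))
  j <- which(tree$parent > 0L)
  Matrix::sparseMatrix(i = tree$parent[j], j = j, x = 1,
                       dims = c(tree$n, tree$n))
}

#' Prune a tree to the branches that carry imaged sites
#'
#' Removes every compartment whose subtree contains no imaged site, i.e.
#' keeps exactly the union of root-to-site paths together with nothing
#' downstream of the last imaged site on each branch.  This mirrors the
#' common practice of dropping dendrites that were never scanned before
#' smoothing.  Side branches between imaged sites are removed unless they
#' themselves contain a site (a keep-rule choice; see the package vignette).
#'
#' @param tree a [dendrite_tree()].
#' @param imaged_sites integer vector of compartment indices with at least
#'   one measurement.
#' @return A pruned [dendrite_tree()] with attribute `index_map`: an integer
#'   vector of length `tree$n` mapping old indices to new ones (`NA` where
#'   removed).
#' @export
prune_tree <- function(tree, imaged_sites) {
  stopifnot(inherits(tree, "dendrite_tree"))
  imaged_sites <- unique(as.integer(imaged_sites))
  if (!length(imaged_sites)) stop("imaged_sites must be nonempty")
  if (any(imaged_sites < 1L | imaged_sites > tree$n))
    stop("imaged_sites out of range")
  keep <- logical(tree$n)
  for (s in imaged_sites) {           # walk to root, marking ancestors
    v <- s
    while (v != 0L && !keep[v]) {
      keep[v] <- TRUE
      v <- tree$parent[v]
    }
  }
  idx_map <- rep(NA_integer_, tree$n)
  idx_map[keep] <- seq_len(sum(keep))
  new_parent <- integer(sum(keep))
  old_kept <- which(keep)
  for (k in seq_along(old_kept)) {
    p <- tree$parent[old_kept[k]]
    new_parent[k] <- if (p == 0L) 0L else idx_map[p]
  }
  out <- dendrite_tree(new_parent,
                       xyz = if (!is.null(tree$xyz)) tree$xyz[keep, , drop = FALSE],
                       radius = if (!is.null(tree$radius)) tree$radius[keep],
                       edge_length = tree$edge_length[keep],
                       type = if (!is.null(tree$type)) tree$type[keep])
  attr(out, "index_map") <- idx_map
  out
}

#' Grow a synthetic dendrite-like tree
#'
#' Random morphology generator used for simulation studies: a main trunk
#' from the soma with side branches spawned at random compartments, each
#' branch a chain of unit-length (1 micrometre) segments with a mild random
#' walk in space.  Statistically this reproduces the features the smoother
#' cares about: a single root, long paths, and branch points.
#'
#' @param n_compartments total number of compartments.
#' @param branch_prob probability per added compartment of opening a new
#'   branch rather than extending an existing tip.
#' @param seed optional RNG seed.
#' @return a [dendrite_tree()].
#' @export
synthetic_tree <- function(n_compartments, branch_prob = 0.05, seed = NULL) {
  stopifnot(n_compartments >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_compartments)
  parent <- integer(n)
  xyz <- matrix(0, n, 3L)
  dir <- matrix(0, n, 3L)
  dir[1L, ] <- c(0, 1, 0)
  if (n > 1L) {
    tips <- 1L
    for (i in 2:n) {
      if (stats::runif(1) < branch_prob && i > 3L) {
        at <- sample.int(i - 1L, 1L)            # branch off anywhere
        d <- stats::rnorm(3); d <- d / sqrt(sum(d^2))
      } else {
        at <- tips[sample.int(length(tips), 1L)] # extend a tip
        d <- dir[at, ] + 0.3 * stats::rnorm(3)
        d <- d / sqrt(sum(d^2))
        tips <- tips[tips != at]
      }
      parent[i] <- at
      xyz[i, ] <- xyz[at, ] + d
      dir[i, ] <- d
      tips <- c(tips, i)
    }
  }
  dendrite_tree(parent, xyz = xyz)
}

#' @export
print.dendrite_tree <- function(x, ...) {
  nb <- sum(tabulate(x$parent[x$parent > 0L], x$n) > 1L)
  cat("Dendritic tree:", x$n, "compartments,",
      sum(!seq_len(x$n) %in% x$parent), "tips,", nb, "branch points\n")
  cat("  max topological distance from soma:",
      format(max(x$topo_distance), digits = 4), "\n")
  invisible(x)
}

#' @export
plot.dendrite_tree <- function(x, sites = NULL, ...) {
  if (is.null(x$xyz)) stop("tree has no coordinates to plot")
  plot(x$xyz[, 1L], x$xyz[, 2L], type = "n", xlab = "x (um)",
       ylab = "y (um)", asp = 1, ...)
  nr <- which(x$parent > 0L)
  segments(x$xyz[nr, 1L], x$xyz[nr, 2L],
           x$xyz[x$parent[nr], 1L], x$xyz[x$parent[nr], 2L])
  points(x$xyz[x$root, 1L], x$xyz[x$root, 2L], pch = 19, cex = 1.2)
  if (!is.null(sites))
    points(x$xyz[sites, 1L], x$xyz[sites, 2L], pch = 21, bg = "red")
  invisible(x)
}
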