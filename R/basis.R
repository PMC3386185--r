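#' Locally supported spline basis on a tree
#'
#' Places bump-function centers along the tree so that consecutive centers
#' on any root-to-leaf path are `spacing` hops apart (the root is always a
#' center), and builds the N x d basis matrix whose column i is a
#' nonnegative bump of the hop distance to center i, truncated to the
#' compartments within `2 * spacing` hops (the center's subdomain).  At a
#' branch point a single bump spreads down every daughter branch inside its
#' subdomain.
#'
#' The default bump is the cubic B-spline kernel of the scaled hop distance
#' `h / spacing`, peak-normalized to 1 so that prior amplitudes on the
#' hidden weights map directly onto transient heights at the centers.  A
#' Gaussian bump (`exp(-(h/spacing)^2)`, same truncation) is available; the
#' exact shape matters little as long as the bumps are smooth and roughly
#' uniformly placed.
#'
#' @param tree a [dendrite_tree()].
#' @param spacing positive integer, topological distance in hops between
#'   neighboring centers.  If it exceeds the tree depth a single bump
#'   centered at the root is returned with a warning.
#' @param form `"bspline"` (default) or `"gaussian"`.
#' @return An object of class `tree_basis`: list with `B` (N x d matrix,
#'   entries >= 0), `centers` (compartment indices), `spacing`, `form`.
#' @export
tree_basis <- function(tree, spacing, form = c("bspline", "gaussian")) {
  stopifnot(inherits(tree, "dendrite_tree"))
  spacing <- as.integer(spacing)
  if (spacing < 1L) stop("spacing must be a positive integer")
  form <- match.arg(form)

  # greedy center placement: distance-to-last-center resets at each center
  kids <- children_list(tree$parent)
  ord <- tree_order(tree$parent, tree$root)
  since <- integer(tree$n)
  is_center <- logical(tree$n)
  is_center[tree$root] <- TRUE
  for (v in ord) {
    for (k in kids[[v]]) {
      s <- since[v] + 1L
      if (s >= spacing) {
        is_center[k] <- TRUE
        since[k] <- 0L
      } else since[k] <- s
    }
  }
  centers <- which(is_center)
  if (length(centers) == 1L && spacing > max(tree$depth))
    warning("spacing exceeds tree depth; using a single bump at the root")

  B <- matrix(0, tree$n, length(centers))
  for (j in seq_along(centers)) {
    h <- hop_distances(tree, centers[j], max_hops = 2L * spacing - 1L)
    in_sup <- is.finite(h)
    t <- h[in_sup] / spacing
    B[in_sup, j] <- if (form == "bspline") bspline_bump(t) else exp(-t^2)
  }
  uncovered <- rowSums(B) <= 0
  if (any(uncovered))
    stop("internal error: compartments with no basis support")  # unreachable
  structure(list(B = B, centers = centers, spacing = spacing, form = form,
                 n = tree$n, d = length(centers)),
            class = "tree_basis")
}

# Cubic B-spline kernel on |t| < 2, peak-normalized to 1 at t = 0.
bspline_bump <- function(t) {
  t <- abs(t)
  out <- numeric(length(t))
  a <- t < 1
  out[a] <- (2 / 3 - t[a]^2 + t[a]^3 / 2) * 1.5
  b <- t >= 1 & t < 2
  out[b] <- ((2 - t[b])^3 / 6) * 1.5
  out
}

#' Evaluate the spatial field from hidden weights
#'
#' Computes `B %*% a` for a single weight vector, or `A %*% t(B)` row-wise
#' for a T x d weight matrix, giving the relative bound-indicator
#' concentration at every compartment.
#'
#' @param basis a [tree_basis()].
#' @param a length-d numeric vector, or T x d matrix of weights.
#' @return length-N vector or T x N matrix.
#' @export
evaluate_field <- function(basis, a) {
  stopifnot(inherits(basis, "tree_basis"))
  if (is.matrix(a)) {
    if (ncol(a) != basis$d) stop("a has ", ncol(a), " columns, basis has ",
                                 basis$d, " functions")
    a %*% t(basis$B)
  } else {
    if (length(a) != basis$d) stop("length(a) != number of basis functions")
    drop(basis$B %*% a)
  }
}

#' Export a basis as a sparse triplet table
#'
#' @param basis a [tree_basis()].
#' @param path optional CSV path; when given the table is written there.
#' @return data.frame with columns `compartment`, `state`, `value`
#'   (nonzero entries only), invisibly when written to file.
#' @export
basis_triplets <- function(basis, path = NULL) {
  stopifnot(inherits(basis, "tree_basis"))
  nz <- which(basis$B > 0, arr.ind = TRUE)
  df <- data.frame(compartment = nz[, 1L], state = nz[, 2L],
                   value = basis$B[nz])
  df <- df[order(df$state, df$compartment), ]
  rownames(df) <- NULL
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' @export
print.tree_basis <- function(x, ...) {
  cat("Tree spline basis:", x$d, "bump functions (", x$form,
      ") on", x$n, "compartments, center spacing", x$spacing, "hops\n")
  invisible(x)
}
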