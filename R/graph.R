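# Weighted k-nearest-neighbour graphs over HEALPix pixels and their
# combinatorial Laplacians. Polynomial filters in L of these graphs
# approximate spherical convolutions.

#' Build the sphere graph at one resolution
#'
#' Connects every pixel to its `k` nearest pixels by chordal distance with
#' Gaussian weights `w_ij = exp(-|x_i - x_j|^2 / (4 t))`, symmetrized by
#' union. The default kernel width is the mean squared distance to the
#' k-th neighbour divided by 4.
#'
#' @param grid A [healpix_grid()].
#' @param k Number of neighbours (default 20; reduced to `n_pix - 1` on
#'   grids with few pixels).
#' @param t Kernel width, or `"auto"`.
#' @return Object of class `sphere_graph`: `adjacency` (sparse symmetric,
#'   zero diagonal), `laplacian` (`L = D - W`), `n_side`, `k`, `t`.
#' @export
build_sphere_graph <- function(grid, k = 20, t = "auto") {
  stopifnot(inherits(grid, "pixel_grid"))
  n <- grid$n_pix
  if (k >= n) stop("k must be smaller than the number of pixels")
  v <- grid$vec
  d2 <- outer(rowSums(v^2), rowSums(v^2), `+`) - 2 * tcrossprod(v)
  d2[d2 < 0] <- 0
  diag(d2) <- Inf
  # tie-inclusive k nearest neighbours: all pixels within the k-th
  # neighbour distance (plus slack) are connected, so symmetric grids do
  # not depend on floating-point tie order
  kth <- apply(d2, 1, function(r) sort(r, partial = k)[k])
  nbr <- d2 <= kth + 1e-9
  if (identical(t, "auto")) t <- mean(kth) / 4
  nbr <- nbr | t(nbr)                 # union symmetrization
  idx <- which(nbr, arr.ind = TRUE)
  W <- Matrix::sparseMatrix(i = idx[, 1], j = idx[, 2],
    x = exp(-d2[idx] / (4 * t)), dims = c(n, n))
  deg <- Matrix::rowSums(W)
  L <- Matrix::Diagonal(x = deg) - W
  structure(list(n_side = grid$n_side, adjacency = W, laplacian = L,
                 k = k, t = t), class = "sphere_graph")
}

#' Graph hierarchy for the pooled resolutions
#'
#' Builds the sphere graphs at the input resolution of each convolution
#' layer (`n_side`, `n_side/2`, ...), each with the same `k` (capped for
#' tiny grids).
#'
#' @param n_side Top resolution (default 16).
#' @param n_layers Number of convolution layers (default 4).
#' @param k Neighbours per pixel (default 20).
#' @return List of `sphere_graph`s, finest first.
#' @export
sphere_graph_hierarchy <- function(n_side = 16, n_layers = 4, k = 20) {
  lapply(seq_len(n_layers), function(l) {
    ns <- n_side / 2^(l - 1)
    if (ns < 1) stop("n_side too small for ", n_layers, " pooling layers")
    g <- healpix_grid(ns)
    build_sphere_graph(g, k = min(k, g$n_pix - 1))
  })
}

#' Polynomial graph convolution
#'
#' Computes `y = sum_{k=0..K} L^k x a_k` by K recursive sparse
#' applications of the Laplacian (no matrix powers are materialized),
#' summing over input channels.
#'
#' @param x `n_pix x C_in` signal matrix.
#' @param graph A `sphere_graph`.
#' @param coeffs `(K+1) x C_in x C_out` coefficient array.
#' @return `n_pix x C_out` matrix.
#' @export
graph_conv <- function(x, graph, coeffs) {
  x <- as.matrix(x)
  K <- dim(coeffs)[1] - 1L
  if (dim(coeffs)[2] != ncol(x)) stop("channel mismatch: x has ", ncol(x),
    " channels, coeffs expect ", dim(coeffs)[2])
  if (nrow(x) != nrow(graph$laplacian)) stop("signal/graph size mismatch")
  y <- x %*% coeffs[1, , , drop = TRUE]
  if (is.null(dim(y))) y <- matrix(y, nrow(x))
  Tk <- x
  for (k in seq_len(K)) {
    Tk <- as.matrix(graph$laplacian %*% Tk)
    ak <- coeffs[k + 1, , , drop = TRUE]
    if (is.null(dim(ak))) ak <- matrix(ak, dim(coeffs)[2], dim(coeffs)[3])
    y <- y + Tk %*% ak
  }
  y
}

#' 4:1 max pooling on nested maps
#'
#' Output pixel `p` is the per-channel maximum over input pixels
#' `4p-3 .. 4p` (nested ordering groups each parent's four children
#' contiguously).
#'
#' @param x `n_pix x C` signal matrix with `n_pix` divisible by 4.
#' @param ordering Must be `"nested"`.
#' @return `(n_pix/4) x C` matrix.
#' @export
pool_maps <- function(x, ordering = "nested") {
  if (!identical(ordering, "nested")) {
    stop("pooling requires nested ordering")
  }
  x <- as.matrix(x)
  n <- nrow(x)
  if (n %% 4 != 0) stop("n_pix not divisible by 4")
  i1 <- seq(1, n, by = 4)
  pmax(x[i1, , drop = FALSE], x[i1 + 1, , drop = FALSE],
       x[i1 + 2, , drop = FALSE], x[i1 + 3, , drop = FALSE])
}
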