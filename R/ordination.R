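# Ordination and tree inference on distance matrices.

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distance matrix, eigendecomposes it and
#' returns the top-k positive-eigenvalue axes scaled by the square roots
#' of their eigenvalues. Sign convention: the first nonzero loading of
#' each axis is positive, so embeddings are reproducible.
#'
#' @param D [distance_matrix()] object (or symmetric matrix).
#' @param k Number of output dimensions (`1 <= k < n`).
#' @return n x k coordinate matrix with labels as row names; eigenvalues
#'   are attached as attribute `"eigenvalues"`.
#' @export
classical_mds <- function(D, k = 2) {
  if (inherits(D, "acr3_dist")) {
    labels <- D$labels
    M <- D$values
  } else {
    M <- as.matrix(D)
    labels <- rownames(M)
    if (is.null(labels)) labels <- as.character(seq_len(nrow(M)))
  }
  n <- nrow(M)
  if (k < 1 || k >= n) stop("dimension error: need 1 <= k < ", n)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (M * M) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  usable <- sum(e$values > tol)
  if (k > usable) {
    stop("dimension error: only ", usable,
         " positive-eigenvalue axes available (requested ", k, ")")
  }
  coords <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(k)]), k, k)
  # sign convention
  for (j in seq_len(k)) {
    nz <- which(abs(coords[, j]) > tol)[1]
    if (!is.na(nz) && coords[nz, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- labels
  colnames(coords) <- paste0("MDS", seq_len(k))
  attr(coords, "eigenvalues") <- e$values
  coords
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining via [ape::nj()]; negative branch-length
#' estimates are clamped to zero and flagged in the attribute
#' `"clamped_edges"`.
#'
#' @param D [distance_matrix()] object (or symmetric matrix) with >= 3
#'   labels.
#' @return An [ape::phylo] object (serializable with [ape::write.tree()]).
#' @export
nj_tree <- function(D) {
  M <- if (inherits(D, "acr3_dist")) D$values else as.matrix(D)
  if (!all(is.finite(M))) stop("input error: non-finite distance")
  if (nrow(M) < 3) stop("input error: need >= 3 labels")
  tr <- ape::nj(M)
  neg <- which(tr$edge.length < 0)
  if (length(neg) > 0) tr$edge.length[neg] <- 0
  attr(tr, "clamped_edges") <- length(neg)
  tr
}

#' Test whether a set of tip labels is monophyletic in an unrooted tree
#'
#' A label set is (unrooted-)monophyletic when some edge of the tree
#' splits exactly that set from the rest.
#'
#' @param tree [ape::phylo] object.
#' @param tips Character vector of tip labels.
#' @return Logical scalar.
#' @export
is_monophyletic_clade <- function(tree, tips) {
  ape::is.monophyletic(ape::unroot(tree), tips)
}
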