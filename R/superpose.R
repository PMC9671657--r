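# Optimal rigid superposition (Kabsch) and RMSD-based structural
# clustering.

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' two matched coordinate sets (reflections corrected via the SVD
#' determinant).
#'
#' @param coords_a,coords_b n x 3 matrices of matched coordinates
#'   (n >= 3). The transform maps `coords_a` onto `coords_b`.
#' @return Object of class `acr3_superposition`: `rotation` (3 x 3,
#'   det = +1), `translation` (length-3), `rmsd`, `n_aligned`, and
#'   `degenerate` (TRUE for collinear/planar-degenerate inputs).
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  A <- as.matrix(coords_a); B <- as.matrix(coords_b)
  if (nrow(A) != nrow(B) || ncol(A) != 3 || ncol(B) != 3) {
    stop("input error: matched n x 3 coordinate matrices required")
  }
  if (nrow(A) < 3) stop("input error: need >= 3 matched points")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- t(A0) %*% B0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  degenerate <- sv$d[2] < 1e-8 * max(sv$d[1], 1e-300)
  resid <- A0 %*% t(R) - B0
  rmsd <- sqrt(mean(rowSums(resid^2)))
  structure(list(rotation = R, translation = cb - as.vector(R %*% ca),
                 rmsd = rmsd, n_aligned = nrow(A),
                 degenerate = degenerate),
            class = "acr3_superposition")
}

#' @export
print.acr3_superposition <- function(x, ...) {
  cat(sprintf("<acr3_superposition> rmsd = %.4f A over %d atoms%s\n",
              x$rmsd, x$n_aligned,
              if (x$degenerate) " (degenerate point set)" else ""))
  invisible(x)
}

#' CA RMSD between two models after sequence matching
#'
#' Sequences are aligned by Needleman-Wunsch; CA coordinates of matched
#' (non-gap) positions are superposed with [kabsch_superpose()].
#'
#' @param model_a,model_b [structure_model()] objects.
#' @return The `acr3_superposition` result (with `rmsd`).
#' @export
superpose_models <- function(model_a, model_b) {
  al <- nw_align(model_a$sequence, model_b$sequence, "protein")
  ga <- strsplit(al$a, "")[[1]]
  gb <- strsplit(al$b, "")[[1]]
  a_pos <- cumsum(ga != "-")
  b_pos <- cumsum(gb != "-")
  both <- which(ga != "-" & gb != "-")
  ca_a <- atom_coords(model_a, "CA")[a_pos[both], , drop = FALSE]
  ca_b <- atom_coords(model_b, "CA")[b_pos[both], , drop = FALSE]
  kabsch_superpose(ca_a, ca_b)
}

#' Cluster structure models by pairwise CA RMSD
#'
#' All-vs-all RMSD (sequence matching + Kabsch) feeds average-linkage
#' hierarchical clustering. The tree is cut at `k` clusters when given,
#' otherwise at the largest gap between consecutive merge heights (all
#' models fall in one cluster when the maximum RMSD is ~0).
#'
#' @param models List of >= 2 [structure_model()] objects.
#' @param k Number of clusters, or `NULL` for the largest-linkage-gap cut.
#' @return Object of class `acr3_clusters`: `labels` (named integer
#'   vector model_id -> cluster), `k`, `rmsd` ([distance_matrix()]),
#'   `hclust` (the tree), `method = "average"`.
#' @export
cluster_structures <- function(models, k = NULL) {
  if (length(models) < 2) stop("input error: need >= 2 models")
  ids <- vapply(models, `[[`, "", "model_id")
  if (anyDuplicated(ids)) {
    ids <- make.unique(ids)
  }
  n <- length(models)
  v <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- superpose_models(models[[i]], models[[j]])$rmsd
      v[i, j] <- r; v[j, i] <- r
    }
  }
  hc <- stats::hclust(stats::as.dist(v), method = "average")
  if (is.null(k)) {
    h <- hc$height
    if (max(v) < 1e-6) {
      k <- 1L
    } else if (n == 2) {
      k <- 2L
    } else {
      gaps <- diff(h)
      k <- n - which.max(gaps)   # cut inside the largest height gap
    }
  }
  labels <- if (k == 1) stats::setNames(rep(1L, n), ids)
  else stats::cutree(hc, k = k)
  structure(list(labels = labels, k = as.integer(k),
                 rmsd = distance_matrix(ids, v, "CA-RMSD"),
                 hclust = hc, method = "average"),
            class = "acr3_clusters")
}

#' @export
print.acr3_clusters <- function(x, ...) {
  cat(sprintf("<acr3_clusters> %d cluster(s), average linkage on CA RMSD\n",
              x$k))
  print(split(names(x$labels), x$labels))
  invisible(x)
}
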