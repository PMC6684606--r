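#' Principal component analysis via singular value decomposition
#'
#' Fits successive orthogonal directions of maximal residual variance on a
#' matrix that the caller has already centered (and optionally scaled, see
#' [scale_center()]).
#'
#' @param x numeric matrix, samples x variables, column-centered.
#' @param n_components number of components to return; truncated with a
#'   warning when it exceeds the matrix rank.
#' @return A list of class `pca_fit`: `scores` (n x a), `loadings`
#'   (p x a, orthonormal columns), `explained_variance` (fraction of total
#'   variance per component, non-increasing), `n_components`.
#' @export
fit_pca <- function(x, n_components = 2L) {
  x <- as.matrix(x)
  sv <- svd(x)
  tol <- max(dim(x)) * .Machine$double.eps * sv$d[1L]
  r <- sum(sv$d > tol)
  if (n_components > r) {
    warning("fit_pca: n_components (", n_components,
            ") exceeds matrix rank (", r, "); truncating")
    n_components <- r
  }
  a <- seq_len(n_components)
  scores <- sv$u[, a, drop = FALSE] %*% diag(sv$d[a], nrow = n_components)
  rownames(scores) <- rownames(x)
  loadings <- sv$v[, a, drop = FALSE]
  rownames(loadings) <- colnames(x)
  colnames(scores) <- colnames(loadings) <- sprintf("PC%d", a)
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = sv$d[a]^2 / sum(sv$d^2),
                 n_components = n_components),
            class = "pca_fit")
}
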