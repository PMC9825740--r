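#' Deterministic 2-D embedding: first two principal directions
#'
#' Standardizes each feature column (by the mean and sd of the fitting set;
#' zero-variance columns are left unscaled) and projects onto the first two
#' principal components. The result is a linear, deterministic map, so
#' distances to the embedded centroid — which is all the bias constraint and
#' the stopping evaluator consume — are stable across runs. Any function with
#' the same signature can be plugged in instead (e.g. a fixed-seed t-SNE
#' wrapper), at the cost of determinism guarantees.
#'
#' @param x numeric matrix (rows = items) to fit on.
#' @param seed ignored (kept so stochastic embeddings share the signature).
#' @return object of class `nanoal_embedding`: list with `points` (fitted
#'   rows embedded, n x 2) and `project(newx)` mapping new rows to 2-D.
#' @export
pca_embedding <- function(x, seed = NULL) {
  x <- as.matrix(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2L, sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  z <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
  sv <- svd(z, nu = 0L, nv = min(2L, ncol(z)))
  rot <- sv$v
  if (ncol(rot) < 2L) rot <- cbind(rot, 0)
  project <- function(newx) {
    newx <- matrix(as.numeric(newx), ncol = length(ctr))
    zz <- sweep(sweep(newx, 2L, ctr), 2L, scl, "/")
    zz %*% rot
  }
  structure(list(points = z %*% rot, project = project),
            class = "nanoal_embedding")
}
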