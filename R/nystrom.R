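#' Fit a Nystroem projection from the landmark kernel block
#'
#' The Nystroem method approximates an `n x n` kernel matrix from the
#' kernel block over `m < n` landmark compounds. Writing the landmark block
#' as `K_AA = U S U'` (symmetric eigendecomposition), the projection matrix
#' is `Gamma = U_r S_r^{-1/2}` over the retained eigenpairs, and the feature
#' embedding of any compound set with kernel rows `K` against the landmarks
#' is `X = K Gamma`, so that `X X' ~ K`. Exact inversion of `K_AA` is
#' numerically unsafe for near-singular kernel blocks, so eigenvalues below
#' `eig_floor` times the largest are discarded (pseudo-inverse semantics).
#'
#' @param K_AA square symmetric [kernel_matrix()] over the landmark
#'   ("main training") compounds.
#' @param eig_floor relative eigenvalue cutoff (default 1e-10).
#' @return object of class `nystrom_projection` with fields `landmark_ids`,
#'   `gamma` (m x r), `eigenvalues` (descending, length r) and `eig_floor`.
#' @export
fit_projection <- function(K_AA, eig_floor = 1e-10) {
  stopifnot(inherits(K_AA, "kernel_matrix"))
  V <- K_AA$values
  if (nrow(V) != ncol(V) || !K_AA$square)
    stop("K_AA must be a square kernel over the landmark set")
  asym <- max(abs(V - t(V)))
  if (asym > 1e-8 * max(1, max(abs(V))))
    stop("K_AA asymmetric beyond tolerance: ", format(asym))
  eg <- eigen((V + t(V)) / 2, symmetric = TRUE)
  lmax <- max(eg$values)
  if (lmax <= 0) stop("K_AA has no positive eigenvalues")
  keep <- eg$values >= eig_floor * lmax
  if (!any(keep)) stop("all eigenvalues below the floor")
  lambda <- eg$values[keep]
  gamma <- eg$vectors[, keep, drop = FALSE] %*% diag(1 / sqrt(lambda),
                                                     nrow = length(lambda))
  rownames(gamma) <- K_AA$row_ids
  structure(list(landmark_ids = K_AA$row_ids, gamma = gamma,
                 eigenvalues = lambda, eig_floor = eig_floor),
            class = "nystrom_projection")
}

#' @export
print.nystrom_projection <- function(x, ...) {
  cat(sprintf("<nystrom_projection> %d landmarks, rank %d, eig_floor %g\n",
              length(x$landmark_ids), length(x$eigenvalues), x$eig_floor))
  invisible(x)
}

#' Embed compounds into the Nystroem feature space
#'
#' @param K_rows [kernel_matrix()] of kernel values between the compounds to
#'   embed (rows) and the landmarks (columns); column ids must equal the
#'   projection's landmark ids in the same order — no silent reordering.
#' @param proj a [fit_projection()] result.
#' @return object of class `nystrom_embedding`: `compound_ids` plus an
#'   `n x r` feature matrix `features`.
#' @export
nystrom_embed <- function(K_rows, proj) {
  stopifnot(inherits(K_rows, "kernel_matrix"),
            inherits(proj, "nystrom_projection"))
  if (!identical(K_rows$col_ids, proj$landmark_ids))
    stop("column ids of K_rows do not match landmark order")
  X <- K_rows$values %*% proj$gamma
  rownames(X) <- K_rows$row_ids
  structure(list(compound_ids = K_rows$row_ids, features = X),
            class = "nystrom_embedding")
}

#' @export
print.nystrom_embedding <- function(x, ...) {
  cat(sprintf("<nystrom_embedding> %d compounds x %d features\n",
              nrow(x$features), ncol(x$features)))
  invisible(x)
}

#' Reconstruct the approximated kernel from embeddings
#'
#' `K ~ X1 X2'`; with both embeddings equal to the landmark embedding this
#' reproduces the landmark block exactly (up to numerical tolerance).
#'
#' @param e1,e2 [nystrom_embed()] results of matching rank.
#' @return a [kernel_matrix()].
#' @export
reconstruct_kernel <- function(e1, e2 = e1) {
  stopifnot(inherits(e1, "nystrom_embedding"),
            inherits(e2, "nystrom_embedding"))
  if (ncol(e1$features) != ncol(e2$features))
    stop("embedding rank mismatch: ", ncol(e1$features), " vs ",
         ncol(e2$features))
  kernel_matrix(tcrossprod(e1$features, e2$features),
                e1$compound_ids, e2$compound_ids,
                name = "nystrom_reconstruction", check = FALSE)
}

#' Serialize / load a Nystroem projection as JSON
#'
#' @param proj a `nystrom_projection`.
#' @param path file path.
#' @return `path` invisibly; the reader returns a `nystrom_projection`.
#' @export
write_projection <- function(proj, path) {
  jsonlite::write_json(
    list(landmark_ids = proj$landmark_ids,
         gamma = proj$gamma, eigenvalues = proj$eigenvalues,
         eig_floor = proj$eig_floor),
    path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_projection
#' @export
read_projection <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  gamma <- as.matrix(x$gamma)
  rownames(gamma) <- x$landmark_ids
  structure(list(landmark_ids = x$landmark_ids, gamma = gamma,
                 eigenvalues = x$eigenvalues, eig_floor = x$eig_floor),
            class = "nystrom_projection")
}
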