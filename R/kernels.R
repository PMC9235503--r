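#' Construct a kernel matrix
#'
#' Compound-by-compound similarity matrix with row/column compound ids.
#' Square kernels (identical row and column ids) are validated for symmetry
#' and for positive semi-definiteness up to numerical noise: the smallest
#' eigenvalue must be at least `-1e-8` times the largest. Larger violations
#' raise an error rather than being clipped silently.
#'
#' @param values numeric matrix.
#' @param row_ids,col_ids compound identifiers; default taken from dimnames.
#' @param name kernel identifier.
#' @param check validate symmetry/PSD of the square case (disable for large
#'   precomputed matrices already validated upstream).
#' @return object of class `kernel_matrix`.
#' @export
kernel_matrix <- function(values, row_ids = rownames(values),
                          col_ids = colnames(values), name = "kernel",
                          check = TRUE) {
  values <- as.matrix(values)
  if (is.null(row_ids) || is.null(col_ids))
    stop("row_ids and col_ids are required")
  stopifnot(length(row_ids) == nrow(values), length(col_ids) == ncol(values))
  dimnames(values) <- list(row_ids, col_ids)
  square <- length(row_ids) == length(col_ids) && all(row_ids == col_ids)
  if (square && check) {
    asym <- max(abs(values - t(values)))
    if (asym > 1e-8 * max(1, max(abs(values))))
      stop("square kernel is asymmetric (max deviation ", format(asym), ")")
    values <- (values + t(values)) / 2
    ev <- eigen(values, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev)))
      stop("kernel is not positive semi-definite: min eigenvalue ",
           format(min(ev)))
  }
  structure(list(values = values, row_ids = row_ids, col_ids = col_ids,
                 name = name, square = square),
            class = "kernel_matrix")
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("<kernel_matrix '%s'> %d x %d%s\n", x$name,
              nrow(x$values), ncol(x$values),
              if (x$square) " (square)" else ""))
  invisible(x)
}

#' @export
dim.kernel_matrix <- function(x) dim(x$values)

#' Probability product kernel between two MS/MS spectra
#'
#' Each spectrum is modelled as a Gaussian mixture over the mass axis: one
#' component per peak, centred at the peak m/z with bandwidth `sigma_m`,
#' weighted by normalized intensity. The kernel is the integral of the
#' product of the two densities, which for Gaussian mixtures has the closed
#' form
#' \deqn{k(a,b) = \sum_i \sum_j w_i w'_j
#'   \exp(-(m_i - m'_j)^2 / (4\sigma_m^2)) / \sqrt{4\pi\sigma_m^2}.}
#' Intensities are normalized to sum 1 internally.
#'
#' @param a,b [spectrum()] objects with at least one peak each.
#' @param sigma_m mass bandwidth in Da (default 0.01).
#' @return non-negative kernel value (unnormalized; see
#'   [normalize_kernel()] for the cosine-normalized variant).
#' @export
ppk <- function(a, b, sigma_m = 0.01) {
  stopifnot(inherits(a, "fpkit_spectrum"), inherits(b, "fpkit_spectrum"),
            sigma_m > 0)
  if (!length(a$mz) || !length(b$mz)) stop("ppk requires non-empty spectra")
  wa <- a$intensity / sum(a$intensity)
  wb <- b$intensity / sum(b$intensity)
  d <- outer(a$mz, b$mz, "-")
  sum(outer(wa, wb) * exp(-d^2 / (4 * sigma_m^2))) / sqrt(4 * pi * sigma_m^2)
}

#' Kernel specification
#'
#' @param name kernel identifier.
#' @param type `"ppk"` (computed natively from spectra) or `"precomputed"`
#'   (e.g. fragmentation-tree kernels loaded from file).
#' @param params list of kernel parameters (`sigma_m` for ppk).
#' @param weight non-negative combination weight.
#' @param path file path for precomputed kernels (TSV, see
#'   [read_kernel_tsv()]).
#' @return object of class `kernel_spec`.
#' @export
kernel_spec <- function(name, type = c("ppk", "precomputed"),
                        params = list(sigma_m = 0.01), weight = 1,
                        path = NULL) {
  type <- match.arg(type)
  stopifnot(weight >= 0)
  if (type == "ppk" && (is.null(params$sigma_m) || params$sigma_m <= 0))
    stop("ppk kernel requires sigma_m > 0")
  structure(list(name = name, type = type, params = params,
                 weight = weight, path = path),
            class = "kernel_spec")
}

#' Evaluate a kernel between two compound sets
#'
#' @param rows,cols lists of `compound_record` objects (use the same list
#'   twice for a square Gram matrix).
#' @param spec a [kernel_spec()].
#' @return [kernel_matrix()] of shape `length(rows) x length(cols)`, indexed
#'   by compound ids; the square case is enforced symmetric.
#' @export
compute_kernel <- function(rows, cols = rows, spec = kernel_spec("ppk")) {
  rid <- vapply(rows, `[[`, character(1), "compound_id")
  cid <- vapply(cols, `[[`, character(1), "compound_id")
  if (spec$type == "precomputed") {
    K <- read_kernel_tsv(spec$path, name = spec$name)
    missing_ids <- c(setdiff(rid, K$row_ids), setdiff(cid, K$col_ids))
    if (length(missing_ids))
      stop("ids missing from precomputed kernel '", spec$name, "': ",
           paste(unique(missing_ids), collapse = ", "))
    return(kernel_matrix(K$values[rid, cid, drop = FALSE], rid, cid,
                         name = spec$name, check = FALSE))
  }
  same <- identical(rid, cid) && identical(rows, cols)
  sp_r <- lapply(rows, `[[`, "spectrum")
  sp_c <- if (same) sp_r else lapply(cols, `[[`, "spectrum")
  norm_w <- function(sp) lapply(sp, function(s) {
    if (!length(s$mz)) stop("ppk requires non-empty spectra")
    s$intensity / sum(s$intensity)
  })
  sigma <- spec$params$sigma_m
  V <- ppk_gram_cpp(lapply(sp_r, `[[`, "mz"), norm_w(sp_r),
                    lapply(sp_c, `[[`, "mz"), norm_w(sp_c),
                    sigma, same, 12)
  kernel_matrix(V, rid, cid, name = spec$name, check = FALSE)
}

#' Cosine-normalize a kernel matrix
#'
#' Divides each entry by the geometric mean of the two self-kernel values,
#' so every compound has unit self-similarity. Idempotent; a square
#' normalized kernel has unit diagonal.
#'
#' @param K a [kernel_matrix()].
#' @param diag_row,diag_col self-kernel values `k(x,x)` for row/column
#'   compounds; default the diagonal of a square `K`.
#' @return normalized `kernel_matrix`.
#' @export
normalize_kernel <- function(K, diag_row = NULL, diag_col = NULL) {
  stopifnot(inherits(K, "kernel_matrix"))
  if (is.null(diag_row)) {
    if (!K$square) stop("diag_row/diag_col required for non-square kernels")
    diag_row <- diag_col <- diag(K$values)
  }
  if (is.null(diag_col)) diag_col <- diag_row
  if (any(diag_row <= 0) || any(diag_col <= 0))
    stop("self-kernel values must be positive for normalization")
  V <- K$values / sqrt(outer(diag_row, diag_col))
  kernel_matrix(V, K$row_ids, K$col_ids, name = K$name, check = FALSE)
}

#' Combine kernels as a weighted sum
#'
#' Multiple-kernel combination: each square input kernel is cosine-
#' normalized, weights are rescaled to sum 1, and the weighted sum is
#' returned. A convex combination of PSD kernels is PSD.
#'
#' @param matrices list of [kernel_matrix()] objects sharing row/col ids.
#' @param weights non-negative weights, one per kernel; sum must be > 0.
#'   Default uniform.
#' @param normalize cosine-normalize each kernel first (square kernels
#'   only; non-square inputs must arrive pre-normalized).
#' @return combined `kernel_matrix`.
#' @export
combine_kernels <- function(matrices, weights = NULL, normalize = TRUE) {
  stopifnot(length(matrices) >= 1)
  if (is.null(weights)) weights <- rep(1, length(matrices))
  stopifnot(length(weights) == length(matrices), all(weights >= 0),
            sum(weights) > 0)
  ref <- matrices[[1]]
  for (K in matrices[-1])
    if (!identical(K$row_ids, ref$row_ids) ||
        !identical(K$col_ids, ref$col_ids))
      stop("kernel id mismatch in combine_kernels")
  weights <- weights / sum(weights)
  V <- matrix(0, nrow(ref$values), ncol(ref$values))
  for (k in seq_along(matrices)) {
    if (weights[k] == 0) next
    Kk <- if (normalize && matrices[[k]]$square)
      normalize_kernel(matrices[[k]]) else matrices[[k]]
    V <- V + weights[k] * Kk$values
  }
  kernel_matrix(V, ref$row_ids, ref$col_ids, name = "combined", check = FALSE)
}

#' Centered-kernel-alignment weights for kernel combination
#'
#' Optional weight-fitting strategy: each kernel's weight is its centered
#' alignment with a target kernel `y y^T` built from the label matrix
#' (alignment = <Kc, Yc> / (||Kc|| ||Yc||), negative alignments floored at
#' 0). Weights are returned unnormalized; [combine_kernels()] rescales.
#'
#' @param matrices list of square [kernel_matrix()] objects on the training
#'   compounds.
#' @param Y numeric matrix of labels (rows aligned with kernel rows).
#' @return non-negative weight vector.
#' @export
alignment_weights <- function(matrices, Y) {
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  T0 <- tcrossprod(Yc)
  Tc <- center_gram(T0)
  nT <- sqrt(sum(Tc^2))
  vapply(matrices, function(K) {
    Kc <- center_gram(K$values)
    a <- sum(Kc * Tc) / (sqrt(sum(Kc^2)) * nT)
    max(a, 0)
  }, numeric(1))
}

center_gram <- function(K) {
  n <- nrow(K)
  H <- diag(n) - matrix(1 / n, n, n)
  H %*% K %*% H
}

#' Read / write kernel matrices as TSV
#'
#' Plain-text exchange format for precomputed kernels (e.g. fragmentation-
#' tree kernels computed by external tooling): a header row of column
#' compound ids, first column holds row ids.
#'
#' @param path file path.
#' @param name kernel identifier attached to the result.
#' @return a [kernel_matrix()] for the reader; `path` invisibly for the
#'   writer.
#' @export
read_kernel_tsv <- function(path, name = "precomputed") {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  kernel_matrix(m, name = name, check = FALSE)
}

#' @rdname read_kernel_tsv
#' @param K a [kernel_matrix()] to serialize.
#' @export
write_kernel_tsv <- function(K, path) {
  df <- data.frame(compound_id = K$row_ids, check.names = FALSE)
  df <- cbind(df, as.data.frame(K$values, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
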