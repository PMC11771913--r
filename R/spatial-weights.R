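# Spatial weight matrices linking point-referenced crash observations:
# k-nearest-neighbour and distance-band rules, row-standardisation, and the
# spectral information (eigenvalues, rho support) the spatial probit sampler
# needs.

new_weight_matrix <- function(W, rule, standardized = FALSE,
                              isolated = integer(0)) {
  structure(list(W = W, n = nrow(W), rule = rule,
                 standardized = standardized, isolated = isolated,
                 eigen_re = NULL, eigen_im = NULL, rho_support = NULL),
            class = "weight_matrix")
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat("Spatial weight matrix:", x$n, "obs,", Matrix::nnzero(x$W),
      "nonzero links (", x$rule,
      if (x$standardized) ", row-standardized" else ", binary", ")\n")
  if (length(x$isolated)) cat("  ", length(x$isolated), "isolated row(s)\n")
  if (!is.null(x$rho_support)) {
    cat("  rho support (", format(x$rho_support[1], digits = 4), ",",
        format(x$rho_support[2], digits = 4), ")\n")
  }
  invisible(x)
}

#' k-nearest-neighbour spatial weights
#'
#' `w_ij = 1` when j is among the k nearest neighbours of i (Euclidean
#' distance on planar coordinates), else 0; generally asymmetric. Distance
#' ties are broken by ascending index, deterministically.
#'
#' @param coords Data frame with `x`, `y` columns or a two-column matrix.
#' @param k Neighbour count; must satisfy `k < n`.
#' @return A `weight_matrix` (sparse, zero diagonal, unstandardised).
#' @export
knn_weights <- function(coords, k = 5) {
  m <- as_coords(coords)
  n <- nrow(m)
  if (k >= n) stop("parameter error: k = ", k, " must be < n = ", n)
  stopifnot(k >= 1)
  d <- as.matrix(stats::dist(m))
  diag(d) <- Inf
  idx <- vapply(seq_len(n),
                function(i) order(d[i, ], seq_len(n))[seq_len(k)],
                integer(k))
  i <- rep(seq_len(n), each = k)
  j <- as.integer(idx)
  W <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  new_weight_matrix(W, rule = sprintf("knn (k = %d)", k))
}

#' Distance-band (contiguity) spatial weights
#'
#' `w_ij = 1` iff `0 < d(i, j) < threshold` (strict, the same convention as
#' the clustering neighbourhood); symmetric. Observations with no neighbour
#' keep an all-zero row — their spatial lag is 0 — and are carried as an
#' isolation warning on the matrix.
#'
#' @inheritParams knn_weights
#' @param threshold Contiguity radius (> 0) in coordinate units.
#' @return A `weight_matrix` (sparse, symmetric, unstandardised).
#' @export
distance_band_weights <- function(coords, threshold) {
  stopifnot(threshold > 0)
  m <- as_coords(coords)
  n <- nrow(m)
  d <- as.matrix(stats::dist(m))
  A <- d < threshold
  diag(A) <- FALSE
  W <- Matrix::Matrix(A * 1, sparse = TRUE)
  isolated <- which(Matrix::rowSums(W) == 0)
  if (length(isolated)) {
    warning(length(isolated), " observation(s) with no neighbour within ",
            threshold, " (isolated rows)")
  }
  new_weight_matrix(W, rule = sprintf("distance band (< %g)", threshold),
                    isolated = isolated)
}

#' Row-standardise a spatial weight matrix
#'
#' Divides each nonzero row by its sum, so the spatial lag is a weighted
#' average of neighbours; zero rows stay zero and remain flagged as
#' isolated. Eigenvalues of the standardised matrix are computed once and
#' cached, and the admissible interval for the spatial dependence parameter,
#' `(1/lambda_min, 1)` with `lambda_min` the smallest real eigenvalue, is
#' stored as `rho_support`. Dense eigendecomposition bounds practical size
#' to a few thousand observations.
#'
#' @param Wm An unstandardised `weight_matrix`.
#' @return The standardised `weight_matrix` with `eigen_re`, `eigen_im`
#'   and `rho_support` filled in.
#' @export
row_standardize <- function(Wm) {
  stopifnot(inherits(Wm, "weight_matrix"))
  if (Wm$standardized) stop("weight matrix is already row-standardized")
  rs <- Matrix::rowSums(Wm$W)
  inv <- ifelse(rs > 0, 1 / rs, 0)
  Ws <- Matrix::Diagonal(x = inv) %*% Wm$W
  out <- new_weight_matrix(methods::as(Ws, "CsparseMatrix"), rule = Wm$rule,
                           standardized = TRUE,
                           isolated = union(Wm$isolated, which(rs == 0)))
  ev <- eigen(as.matrix(Ws), only.values = TRUE)$values
  out$eigen_re <- Re(ev)
  out$eigen_im <- if (is.complex(ev)) Im(ev) else rep(0, length(ev))
  real_ev <- out$eigen_re[abs(out$eigen_im) < 1e-8]
  lam_min <- min(real_ev)
  lower <- if (lam_min < 0) 1 / lam_min else -1
  out$rho_support <- c(lower, 1)
  out
}

#' Write / read a weight matrix as sparse-triplet text
#'
#' Format: a `#`-prefixed header with `n`, the rule and the standardisation
#' flag, then one `i j w` line per nonzero entry (0-based indices,
#' tab-separated).
#'
#' @param Wm A `weight_matrix`.
#' @param path File path.
#' @export
write_weights <- function(Wm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n=%d standardized=%s rule=%s", Wm$n,
                     Wm$standardized, Wm$rule), con)
  T3 <- methods::as(methods::as(Wm$W, "CsparseMatrix"), "TsparseMatrix")
  df <- data.frame(i = T3@i, j = T3@j, w = T3@x)
  df <- df[order(df$i, df$j), ]
  utils::write.table(df, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  hdr <- readLines(path, n = 1)
  n <- as.integer(sub(".*n=([0-9]+).*", "\\1", hdr))
  std <- grepl("standardized=TRUE", hdr)
  rule <- sub(".*rule=", "", hdr)
  df <- utils::read.table(path, skip = 1, col.names = c("i", "j", "w"))
  W <- Matrix::sparseMatrix(i = df$i + 1L, j = df$j + 1L, x = df$w,
                            dims = c(n, n))
  out <- new_weight_matrix(W, rule = rule, standardized = std,
                           isolated = which(Matrix::rowSums(W) == 0 &
                                            Matrix::colSums(W) == 0))
  if (std) {
    # re-derive the spectral cache; it is not serialised
    ev <- eigen(as.matrix(W), only.values = TRUE)$values
    out$eigen_re <- Re(ev)
    out$eigen_im <- if (is.complex(ev)) Im(ev) else rep(0, length(ev))
    real_ev <- out$eigen_re[abs(out$eigen_im) < 1e-8]
    lam_min <- min(real_ev)
    out$rho_support <- c(if (lam_min < 0) 1 / lam_min else -1, 1)
  }
  out
}
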