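#' Sparsemax: Euclidean projection onto the probability simplex
#'
#' Returns `argmin_{p in simplex} ||p - v||^2` by the sorted-threshold
#' (water-filling) algorithm. Unlike softmax, the projection yields exact
#' zeros, which is what lets the deconvolution output genuinely sparse
#' cell-type compositions. Translation-invariant: adding a constant to all
#' coordinates leaves the result unchanged.
#'
#' @param v numeric vector, or a matrix to project row-wise.
#' @return simplex vector (or matrix of simplex rows) of the same shape.
#' @export
sparsemax <- function(v) {
  if (is.matrix(v)) return(sparsemax_rows(v))
  if (any(!is.finite(v))) stop("sparsemax input must be finite", call. = FALSE)
  drop(sparsemax_rows(matrix(v, 1)))
}

# fully vectorized row-wise projection
sparsemax_rows <- function(V) {
  if (any(!is.finite(V))) stop("sparsemax input must be finite", call. = FALSE)
  n <- nrow(V)
  k <- ncol(V)
  if (k == 1) return(matrix(1, n, 1, dimnames = dimnames(V)))
  # sort each row in decreasing order (column-free trick via order())
  o <- order(row(V), -V)
  Z <- matrix(V[o], n, k, byrow = TRUE)
  css <- Z %*% upper.tri(diag(k), diag = TRUE)  # row-wise cumulative sums
  holds <- 1 + sweep(Z, 2, seq_len(k), "*") > css
  supp <- rowSums(holds)  # support size; >= 1 always
  tau <- (css[cbind(seq_len(n), supp)] - 1) / supp
  P <- pmax(V - tau, 0)
  dimnames(P) <- dimnames(V)
  P
}

# backward pass: J = diag(s) - s s^T / |S| restricted to the support S
sparsemax_backward <- function(P, dP) {
  S <- P > 0
  cnt <- rowSums(S)
  ssum <- rowSums(dP * S)
  (dP - ssum / cnt) * S
}
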