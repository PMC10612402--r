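#' Construct a reference signature profile
#'
#' @param u T x G non-negative matrix of per-type mean expression on the
#'   median-library scale.
#' @param beta length-G positive vector of gene inverse-dispersions.
#' @param type_order,gene_ids dimension identifiers.
#' @return list of class `reference_profile`.
#' @export
reference_profile <- function(u, beta, type_order = rownames(u),
                              gene_ids = colnames(u)) {
  u <- as.matrix(u)
  if (any(!is.finite(u)) || any(u < 0)) {
    stop("u must be finite and non-negative", call. = FALSE)
  }
  if (any(!is.finite(beta)) || any(beta <= 0)) {
    stop("beta must be finite and positive", call. = FALSE)
  }
  if (nrow(u) != length(type_order) || ncol(u) != length(gene_ids) ||
      length(beta) != length(gene_ids)) {
    stop("profile dimensions are inconsistent", call. = FALSE)
  }
  dimnames(u) <- list(type_order, gene_ids)
  structure(list(u = u, beta = setNames(as.numeric(beta), gene_ids),
                 type_order = as.character(type_order),
                 gene_ids = as.character(gene_ids)),
            class = "reference_profile")
}

#' @export
print.reference_profile <- function(x, ...) {
  cat("reference_profile:", length(x$type_order), "cell types x",
      length(x$gene_ids), "genes\n")
  cat("  beta range:", format(range(x$beta), digits = 3), "\n")
  invisible(x)
}

#' Estimate cell-type expression signatures from a labelled reference
#'
#' Fits, per gene, a negative binomial model to the single-cell reference:
#' cell `c` of type `t` has counts `x_cg ~ NB(o_c * u_tg, beta_g)` where
#' `o_c` is a fixed library-size offset (total count of the cell divided by
#' the median total count, so `u` lives on a "median library" scale) and
#' `beta_g` is one inverse-dispersion per gene shared across types.
#' Maximization alternates damped Newton updates on `log u` (per type and
#' gene) and `log beta` (per gene); both blocks use step halving so the
#' log-likelihood never decreases. Convergence is declared when the
#' relative change in total log-likelihood drops below `tol`.
#'
#' Genes with no counts in a type get `u_tg = 0` exactly; genes with no
#' counts anywhere additionally get `beta_g` at the configured floor
#' (1e-3). `beta` is clamped to \[1e-3, 1e4\] for numerical hygiene.
#'
#' @param reference cells x genes count matrix (see [count_matrix()]).
#' @param labels a [cell_labels()] object aligned with `reference` rows.
#' @param max_iter maximum outer iterations (default 100).
#' @param tol relative log-likelihood tolerance (default 1e-6).
#' @param offsets optional fixed per-cell offsets; by default computed as
#'   total count / median total count.
#' @return a `reference_profile`; attribute `"loglik"` holds the per-
#'   iteration total log-likelihood, attribute `"converged"` the status.
#' @export
estimate_signatures <- function(reference, labels, max_iter = 100,
                                tol = 1e-6, offsets = NULL) {
  if (!identical(rownames(reference), labels$row_ids)) {
    if (!setequal(rownames(reference), labels$row_ids)) {
      stop("labels do not cover the reference cells", call. = FALSE)
    }
    reference <- reference[labels$row_ids, , drop = FALSE]
  }
  types <- labels$type_order
  idx <- split(seq_len(nrow(reference)), factor(labels$labels, types))
  small <- names(idx)[vapply(idx, length, 1L) < 2]
  if (length(small) > 0) {
    stop("cell types with fewer than 2 cells: ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  G <- ncol(reference)
  Tt <- length(types)
  totals <- rowSums(reference)
  if (is.null(offsets)) {
    offsets <- totals / median(totals)
  }

  # Poisson MLE initialization: u = sum(x) / sum(o) within type
  u <- matrix(0, Tt, G, dimnames = list(types, colnames(reference)))
  for (t in seq_len(Tt)) {
    os <- sum(offsets[idx[[t]]])
    if (os > 0) {
      u[t, ] <- colSums(reference[idx[[t]], , drop = FALSE]) / os
    }
  }
  active <- u > 0  # (t, g) cells that are free parameters

  type_of <- match(labels$labels, types)
  mu_all <- u[type_of, , drop = FALSE] * offsets
  # method-of-moments start for beta: var = mu + mu^2 / beta
  num <- colSums(mu_all^2)
  den <- colSums((reference - mu_all)^2 - mu_all)
  beta <- ifelse(num > 0 & den > 0,
                 pmin(pmax(num / den, BETA_MIN), BETA_MAX), BETA_MAX)
  beta[colSums(reference) == 0] <- BETA_MIN

  ll_trace <- sig_total_ll(reference, idx, offsets, u, beta)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    u <- sig_update_u(reference, idx, offsets, u, beta, active)
    beta <- sig_update_beta(reference, type_of, offsets, u, beta)
    ll <- sig_total_ll(reference, idx, offsets, u, beta)
    ll_trace <- c(ll_trace, ll)
    prev <- ll_trace[length(ll_trace) - 1]
    if (abs(ll - prev) <= tol * (abs(prev) + 1)) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("signature estimation did not converge in ", max_iter,
            " iterations; returning last iterate", call. = FALSE)
  }
  out <- reference_profile(u, beta, types, colnames(reference))
  attr(out, "loglik") <- ll_trace
  attr(out, "converged") <- converged
  out
}

sig_total_ll <- function(X, idx, offsets, u, beta) {
  ll <- 0
  for (t in seq_along(idx)) {
    Xt <- X[idx[[t]], , drop = FALSE]
    Mu <- outer(offsets[idx[[t]]], u[t, ])
    ll <- ll + sum(nb_log_pmf(Xt, Mu, beta))
  }
  ll
}

# one damped Newton ascent step on log u, per (type, gene), with halving
sig_update_u <- function(X, idx, offsets, u, beta, active) {
  for (t in seq_along(idx)) {
    free <- which(active[t, ])
    if (length(free) == 0) next
    Xt <- X[idx[[t]], free, drop = FALSE]
    o <- offsets[idx[[t]]]
    bt <- beta[free]
    ut <- u[t, free]
    B <- per_gene(bt, nrow(Xt), length(free))
    Mu <- outer(o, ut)
    R <- Mu / (B + Mu)
    grad <- colSums(Xt) - colSums((Xt + B) * R)            # d ll / d log u
    hess <- -colSums((Xt + B) * B * Mu / (B + Mu)^2)       # always < 0
    step <- grad / pmax(-hess, 1e-12)
    step <- pmin(pmax(step, -4), 4)  # trust region in log space
    ll0 <- colSums(nb_log_pmf(Xt, Mu, B))
    for (h in 1:25) {
      prop <- ut * exp(step)
      ll1 <- colSums(nb_log_pmf(Xt, outer(o, prop), B))
      bad <- ll1 < ll0 - 1e-10
      if (!any(bad)) break
      step[bad] <- step[bad] / 2
    }
    improved <- ll1 >= ll0 - 1e-10
    ut[improved] <- ut[improved] * exp(step[improved])
    u[t, free] <- ut
  }
  u
}

# one damped Newton ascent step on log beta, per gene, with halving
sig_update_beta <- function(X, type_of, offsets, u, beta) {
  Mu <- u[type_of, , drop = FALSE] * offsets
  n <- nrow(X)
  G <- ncol(X)
  B <- per_gene(beta, n, G)
  Mu_f <- pmax(Mu, MU_FLOOR)
  d1 <- colSums(digamma(X + B) - digamma(B) + log(B) + 1 -
                  log(B + Mu_f) - (X + B) / (B + Mu_f))
  d2 <- colSums(trigamma(X + B) - trigamma(B) + 1 / B - 1 / (B + Mu_f) -
                  (Mu_f - X) / (B + Mu_f)^2)
  # Newton in zeta = log beta
  g_z <- beta * d1
  h_z <- beta * d1 + beta^2 * d2
  step <- ifelse(h_z < 0, -g_z / h_z, sign(g_z) * 0.5)
  step[g_z == 0] <- 0
  step <- pmin(pmax(step, -2), 2)
  ll_gene <- function(b) {
    colSums(nb_log_pmf(X, Mu, b))
  }
  ll0 <- ll_gene(beta)
  for (h in 1:25) {
    prop <- pmin(pmax(beta * exp(step), BETA_MIN), BETA_MAX)
    ll1 <- ll_gene(prop)
    bad <- ll1 < ll0 - 1e-10
    if (!any(bad)) break
    step[bad] <- step[bad] / 2
  }
  ok <- ll1 >= ll0 - 1e-10
  beta[ok] <- pmin(pmax(beta[ok] * exp(step[ok]), BETA_MIN), BETA_MAX)
  zero_gene <- colSums(X) == 0
  beta[zero_gene] <- BETA_MIN
  beta
}
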