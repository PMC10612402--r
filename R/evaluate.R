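#' Build a k-nearest-neighbour spatial weight graph
#'
#' Binary kNN adjacency with row-standardized weights, the input for
#' Moran's I. Ties in distance are broken by spot order (deterministic).
#'
#' @param coords a [spot_coords()] object.
#' @param k number of neighbours (default 6, a hexagonal-lattice-like
#'   neighbourhood).
#' @return sparse N x N row-standardized weight matrix (class from the
#'   Matrix package), rownames/colnames = spot ids.
#' @export
knn_graph <- function(coords, k = 6) {
  xy <- coords$xy
  n <- nrow(xy)
  if (n < 2) stop("need at least 2 spots", call. = FALSE)
  k <- min(k, n - 1)
  d <- as.matrix(dist(xy))
  diag(d) <- Inf
  idx <- apply(d, 1, function(row) order(row)[seq_len(k)])
  W <- Matrix::sparseMatrix(
    i = rep(seq_len(n), each = k),
    j = as.vector(idx),
    x = 1 / k, dims = c(n, n),
    dimnames = list(coords$row_ids, coords$row_ids))
  W
}

#' Moran's I spatial autocorrelation
#'
#' `I = (n / sum(W)) * sum_ij w_ij (x_i - xbar)(x_j - xbar) /
#' sum_i (x_i - xbar)^2`. Positive for spatially clustered fields,
#' near `-1/(n-1)` under spatial randomness. A constant input has no
#' defined autocorrelation and returns `NA` with a warning.
#'
#' @param values per-spot numeric vector.
#' @param graph weight matrix (ideally row-standardized, e.g. from
#'   [knn_graph()]).
#' @return scalar Moran's I, or `NA` for a constant input.
#' @export
morans_i <- function(values, graph) {
  n <- length(values)
  if (n != nrow(graph)) stop("values do not match the graph", call. = FALSE)
  xc <- values - mean(values)
  denom <- sum(xc^2)
  if (denom == 0) {
    warning("constant input: Moran's I is undefined", call. = FALSE)
    return(NA_real_)
  }
  num <- sum(xc * as.numeric(graph %*% xc))
  (n / sum(graph)) * num / denom
}

#' Jensen-Shannon distance between two probability vectors
#'
#' Square root of the Jensen-Shannon divergence with base-2 logarithms: a
#' bounded metric in \[0, 1\], 0 iff `p = q`, 1 for disjoint supports.
#' Inputs off the simplex by at most 1e-6 are renormalized with a warning.
#'
#' @param p,q non-negative vectors summing to 1.
#' @return scalar in \[0, 1\].
#' @export
js_distance <- function(p, q) {
  if (length(p) != length(q)) stop("length mismatch", call. = FALSE)
  if (any(p < 0) || any(q < 0)) {
    stop("probability vectors must be non-negative", call. = FALSE)
  }
  renorm <- function(v) {
    s <- sum(v)
    if (abs(s - 1) > 1e-6) {
      stop("input does not sum to 1 (sum = ", format(s), ")", call. = FALSE)
    }
    if (s != 1) {
      # deviations beyond machine precision get a warning; epsilon-level
      # drift from upstream arithmetic is fixed silently
      if (abs(s - 1) > 1e-12) {
        warning("renormalizing input off the simplex by ",
                format(abs(s - 1)), call. = FALSE)
      }
      v <- v / s
    }
    v
  }
  p <- renorm(p)
  q <- renorm(q)
  m <- (p + q) / 2
  kl2 <- function(a, b) {
    i <- a > 0
    sum(a[i] * (log2(a[i]) - log2(b[i])))
  }
  div <- 0.5 * kl2(p, m) + 0.5 * kl2(q, m)
  sqrt(max(div, 0))
}

#' Spearman correlation between proportions and marker expression
#'
#' For each (cell type, marker gene) pair, the Spearman rank correlation
#' between the type's inferred proportion and the marker's expression
#' across all spots (average ranks for ties). Zero-variance vectors give
#' `NA`, never an imputed 0. Markers absent from the spatial matrix are
#' skipped with a message.
#'
#' @param props N x T proportion matrix (colnames = cell types).
#' @param spatial N x G spatial count matrix (same spots).
#' @param markers named list mapping cell type to marker gene ids (see
#'   [read_markers()]).
#' @return tibble with columns `cell_type`, `gene`, `rho`.
#' @export
marker_correlation <- function(props, spatial, markers) {
  stopifnot(nrow(props) == nrow(spatial))
  rows <- list()
  for (ct in names(markers)) {
    if (!ct %in% colnames(props)) {
      stop("marker set references unknown cell type: ", ct, call. = FALSE)
    }
    for (g in markers[[ct]]) {
      if (!g %in% colnames(spatial)) {
        message("marker gene not in spatial data, skipped: ", g)
        next
      }
      x <- props[, ct]
      y <- spatial[, g]
      rho <- if (sd(x) == 0 || sd(y) == 0) {
        NA_real_
      } else {
        cor(x, y, method = "spearman")
      }
      rows[[length(rows) + 1]] <- tibble(cell_type = ct, gene = g,
                                         rho = rho)
    }
  }
  if (length(rows) == 0) {
    return(tibble(cell_type = character(), gene = character(),
                  rho = numeric()))
  }
  do.call(rbind, rows)
}

#' Full evaluation of a deconvolution run
#'
#' Per cell type: the Spearman correlations of its proportion field with
#' its marker genes and the Moran's I of the proportion field. Per spot:
#' the Jensen-Shannon distance between the inferred composition and a
#' marker-derived reference composition (each type scored by the mean
#' expression of its markers at the spot, normalized across types).
#' Spots where no marker is detected carry no information and get `NA`.
#'
#' @param props N x T proportion matrix.
#' @param spatial N x G spatial counts (same spots).
#' @param coords [spot_coords()] for the spots.
#' @param markers named list of marker gene ids per cell type.
#' @param k_neighbors kNN graph size for Moran's I (default 6).
#' @return list of class `spotsparse_eval`: `per_type` tibble
#'   (`cell_type`, `n_markers`, `median_rho`, `morans_i`), `per_spot`
#'   tibble (`spot`, `js`), `summary` tibble of medians (undefined values
#'   excluded, not imputed).
#' @export
evaluate_run <- function(props, spatial, coords, markers, k_neighbors = 6) {
  stopifnot(nrow(props) == nrow(spatial),
            nrow(props) == length(coords$row_ids))
  mc <- marker_correlation(props, spatial, markers)
  W <- knn_graph(coords, k = k_neighbors)
  types <- intersect(names(markers), colnames(props))

  per_type <- do.call(rbind, lapply(types, function(ct) {
    rhos <- mc$rho[mc$cell_type == ct]
    mi <- suppressWarnings(morans_i(props[, ct], W))
    tibble(cell_type = ct, n_markers = sum(mc$cell_type == ct),
           median_rho = median(rhos, na.rm = TRUE), morans_i = mi)
  }))

  # marker-derived reference composition per spot
  score <- sapply(types, function(ct) {
    gs <- intersect(markers[[ct]], colnames(spatial))
    if (length(gs) == 0) return(rep(0, nrow(spatial)))
    rowMeans(spatial[, gs, drop = FALSE])
  })
  tot <- rowSums(score)
  js <- rep(NA_real_, nrow(props))
  ok <- which(tot > 0)
  P <- props[, types, drop = FALSE]
  Psum <- rowSums(P)
  for (i in ok) {
    if (Psum[i] <= 0) next
    js[i] <- js_distance(P[i, ] / Psum[i], score[i, ] / tot[i])
  }
  per_spot <- tibble(spot = rownames(props) %||% as.character(seq_len(nrow(props))),
                     js = js)
  summary <- tibble(
    median_rho = median(mc$rho, na.rm = TRUE),
    median_morans_i = median(per_type$morans_i, na.rm = TRUE),
    median_js = median(js, na.rm = TRUE))
  structure(list(per_type = per_type, per_spot = per_spot,
                 summary = summary),
            class = "spotsparse_eval")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.spotsparse_eval <- function(x, ...) {
  cat("spotsparse_eval over", nrow(x$per_type), "cell types\n")
  print(x$summary)
  invisible(x)
}
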