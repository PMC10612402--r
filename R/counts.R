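#' Construct a validated spot-by-gene count matrix
#'
#' Counts are stored as a plain numeric matrix (rows = spots or cells,
#' columns = genes) with unique dimnames. Values must be non-negative
#' integers; they are kept in double storage so totals beyond 2^31 do not
#' overflow.
#'
#' @param values numeric matrix of non-negative integers.
#' @param row_ids character vector of unique spot/cell identifiers
#'   (defaults to `rownames(values)`).
#' @param gene_ids character vector of unique gene identifiers (defaults to
#'   `colnames(values)`).
#' @return the validated matrix with dimnames set.
#' @export
count_matrix <- function(values, row_ids = rownames(values),
                         gene_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("counts must be a numeric matrix", call. = FALSE)
  }
  if (is.null(row_ids)) row_ids <- paste0("spot", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(values)))
  if (length(row_ids) != nrow(values) || length(gene_ids) != ncol(values)) {
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(row_ids)) {
    stop("duplicate row identifiers: ",
         paste(unique(row_ids[duplicated(row_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(values) | values < 0 | values != floor(values))
  if (length(bad) > 0) {
    i <- arrayInd(bad[1], dim(values))
    stop(sprintf(
      "counts must be non-negative integers; offending entry at row %d ('%s'), column %d ('%s'): %s",
      i[1], row_ids[i[1]], i[2], gene_ids[i[2]],
      format(values[bad[1]])), call. = FALSE)
  }
  storage.mode(values) <- "double"
  dimnames(values) <- list(as.character(row_ids), as.character(gene_ids))
  values
}

#' Restrict two count matrices to their shared genes
#'
#' The deconvolution model requires the single-cell reference and the
#' spatial data to live in one gene space. Both matrices are restricted to
#' the intersection of their gene identifiers, in lexicographic order so
#' that the shared ordering is deterministic.
#'
#' @param a,b count matrices with gene identifiers as column names.
#' @return a list with elements `a` and `b`, both restricted to the shared
#'   genes in the same (lexicographic) order.
#' @export
align_genes <- function(a, b) {
  ga <- colnames(a)
  gb <- colnames(b)
  if (is.null(ga) || is.null(gb)) {
    stop("both matrices need gene identifiers as column names", call. = FALSE)
  }
  shared <- sort(intersect(ga, gb), method = "radix")
  if (length(shared) == 0) {
    stop("no shared genes between the two matrices", call. = FALSE)
  }
  list(a = a[, shared, drop = FALSE], b = b[, shared, drop = FALSE])
}

#' Construct a cell-type label vector
#'
#' @param row_ids cell identifiers, aligned with a reference count matrix.
#' @param labels cell-type name per cell.
#' @param type_order canonical ordering of the distinct cell types; defaults
#'   to the sorted unique labels.
#' @return a list of class `cell_labels` with fields `row_ids`, `labels`,
#'   `type_order`.
#' @export
cell_labels <- function(row_ids, labels,
                        type_order = sort(unique(labels), method = "radix")) {
  row_ids <- as.character(row_ids)
  labels <- as.character(labels)
  if (length(row_ids) != length(labels)) {
    stop("row_ids and labels must have the same length", call. = FALSE)
  }
  if (!all(labels %in% type_order)) {
    stop("labels outside type_order: ",
         paste(setdiff(labels, type_order), collapse = ", "), call. = FALSE)
  }
  if (length(type_order) < 2) {
    stop("at least two distinct cell types are required", call. = FALSE)
  }
  structure(list(row_ids = row_ids, labels = labels,
                 type_order = type_order),
            class = "cell_labels")
}

#' Construct spot coordinates
#'
#' Planar coordinates for spatial spots; only needed for spatial statistics
#' (Moran's I), never for the model itself.
#'
#' @param row_ids spot identifiers.
#' @param xy numeric N x 2 matrix of planar coordinates.
#' @return a list of class `spot_coords`.
#' @export
spot_coords <- function(row_ids, xy) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2 || !is.numeric(xy)) {
    stop("coordinates must be a numeric N x 2 matrix", call. = FALSE)
  }
  if (length(row_ids) != nrow(xy)) {
    stop("row_ids length must match coordinate rows", call. = FALSE)
  }
  rownames(xy) <- as.character(row_ids)
  colnames(xy) <- c("x", "y")
  structure(list(row_ids = as.character(row_ids), xy = xy),
            class = "spot_coords")
}

# rows-on-simplex check used by several modules
validate_proportions <- function(p, tol = 1e-6) {
  p <- as.matrix(p)
  if (any(!is.finite(p)) || any(p < -tol) || any(p > 1 + tol)) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  rs <- rowSums(p)
  if (any(abs(rs - 1) > tol)) {
    stop("proportion rows must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")", call. = FALSE)
  }
  invisible(p)
}
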