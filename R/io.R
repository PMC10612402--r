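#' Read a spot-by-gene count matrix
#'
#' Two on-disk layouts are supported:
#' \describe{
#'   \item{`dense_tsv`}{tab-separated table, header row = gene ids, first
#'     column = spot ids, one row per spot.}
#'   \item{`mtx_triplet`}{a directory (or a `matrix.mtx` path) holding the
#'     CellRanger-style triplet `matrix.mtx` (genes x spots, Matrix Market
#'     coordinate format), `features.tsv` (gene ids, first column) and
#'     `barcodes.tsv` (spot ids). The matrix is transposed to spots x genes
#'     in memory.}
#' }
#'
#' @param path file (dense TSV) or directory / `matrix.mtx` path (triplet).
#' @param format `"dense_tsv"` or `"mtx_triplet"`; guessed from `path` by
#'   default.
#' @return a validated count matrix (see [count_matrix()]), gene order as in
#'   the file.
#' @export
read_counts <- function(path, format = c("auto", "dense_tsv", "mtx_triplet")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path) || grepl("\\.mtx$", path)) {
      "mtx_triplet"
    } else {
      "dense_tsv"
    }
  }
  if (format == "dense_tsv") {
    read_counts_dense(path)
  } else {
    read_counts_mtx(path)
  }
}

read_counts_dense <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("malformed dense counts table: ", path, call. = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(apply(df[, -1, drop = FALSE], 1,
                       function(r) any(is.na(suppressWarnings(as.numeric(r))))))
    stop(sprintf("non-numeric count entries in %s, data line %d", path,
                 bad[1]), call. = FALSE)
  }
  nonint <- which(rowSums(m != floor(m) | m < 0) > 0)
  if (length(nonint) > 0) {
    stop(sprintf("non-integer or negative counts in %s, data line %d",
                 path, nonint[1]), call. = FALSE)
  }
  count_matrix(m, row_ids = ids, gene_ids = colnames(m))
}

read_counts_mtx <- function(path) {
  dirp <- if (dir.exists(path)) path else dirname(path)
  mtx <- if (dir.exists(path)) file.path(path, "matrix.mtx") else path
  if (!file.exists(mtx)) stop("matrix.mtx not found under ", path, call. = FALSE)
  feat <- first_existing(file.path(dirp, c("features.tsv", "genes.tsv")))
  bc <- file.path(dirp, "barcodes.tsv")
  if (is.null(feat) || !file.exists(bc)) {
    stop("MTX triplet requires sibling features.tsv (or genes.tsv) and barcodes.tsv in ",
         dirp, call. = FALSE)
  }
  m <- tryCatch(Matrix::readMM(mtx),
                error = function(e) stop("malformed Matrix Market file ", mtx,
                                         ": ", conditionMessage(e),
                                         call. = FALSE))
  genes <- read.delim(feat, header = FALSE, stringsAsFactors = FALSE)[[1]]
  spots <- read.delim(bc, header = FALSE, stringsAsFactors = FALSE)[[1]]
  if (nrow(m) != length(genes) || ncol(m) != length(spots)) {
    stop(sprintf("MTX dimensions (%d x %d) do not match features (%d) / barcodes (%d)",
                 nrow(m), ncol(m), length(genes), length(spots)), call. = FALSE)
  }
  count_matrix(t(as.matrix(m)), row_ids = spots, gene_ids = genes)
}

first_existing <- function(paths) {
  hit <- paths[file.exists(paths)]
  if (length(hit) == 0) NULL else hit[1]
}

#' Write a count matrix
#'
#' @param counts validated count matrix.
#' @param path output file (dense TSV) or directory (MTX triplet).
#' @param format `"dense_tsv"` or `"mtx_triplet"`.
#' @export
write_counts <- function(counts, path,
                         format = c("dense_tsv", "mtx_triplet")) {
  format <- match.arg(format)
  if (format == "dense_tsv") {
    df <- data.frame(spot = rownames(counts), counts, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(methods::as(Matrix::Matrix(t(counts), sparse = TRUE),
                                "generalMatrix"),
                    file.path(path, "matrix.mtx"))
    writeLines(colnames(counts), file.path(path, "features.tsv"))
    writeLines(rownames(counts), file.path(path, "barcodes.tsv"))
  }
  invisible(path)
}

#' Write / read per-spot cell-type proportions
#'
#' TSV with spot ids in the first column and one column per cell type;
#' values are written at full double precision so a round trip is the
#' identity to well below 1e-6.
#'
#' @param props numeric matrix, rows on the probability simplex, rownames =
#'   spot ids, colnames = cell types.
#' @param path output / input file.
#' @export
write_proportions <- function(props, path) {
  props <- as.matrix(props)
  if (nrow(props) > 0) validate_proportions(props)
  df <- data.frame(spot = rownames(props), props, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (nrow(props) == 0) {
    df <- as.data.frame(matrix(nrow = 0, ncol = ncol(props) + 1))
    names(df) <- c("spot", colnames(props))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_proportions
#' @export
read_proportions <- function(path) {
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}

#' Read / write spot coordinates (TSV: spot, x, y)
#' @param path TSV file with header columns `spot`, `x`, `y`.
#' @export
read_coordinates <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("coordinates need columns spot, x, y", call. = FALSE)
  spot_coords(df[[1]], as.matrix(df[, 2:3]))
}

#' @rdname read_coordinates
#' @param coords a [spot_coords()] object.
#' @export
write_coordinates <- function(coords, path) {
  df <- data.frame(spot = coords$row_ids, x = coords$xy[, 1],
                   y = coords$xy[, 2])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write cell-type labels (TSV: cell, cell_type)
#' @param path TSV file with header columns `cell`, `cell_type`.
#' @export
read_labels <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("labels need columns cell, cell_type", call. = FALSE)
  cell_labels(df[[1]], df[[2]])
}

#' @rdname read_labels
#' @param labels a [cell_labels()] object.
#' @export
write_labels <- function(labels, path) {
  df <- data.frame(cell = labels$row_ids, cell_type = labels$labels)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read marker-gene lists (TSV: cell_type, gene, rank)
#'
#' @param path TSV with header columns `cell_type`, `gene`, `rank`
#'   (rank 1 = top marker).
#' @return named list mapping cell type to its marker gene ids ordered by
#'   rank.
#' @export
read_markers <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("cell_type", "gene", "rank") %in% names(df))) {
    stop("marker table needs columns cell_type, gene, rank", call. = FALSE)
  }
  df <- df[order(df$cell_type, df$rank), ]
  split(df$gene, df$cell_type)
}

#' Write / read a reference signature profile as a TSV pair
#'
#' The cell-type mean matrix `u` goes to `<prefix>_u.tsv` (types x genes,
#' first column = cell type) and the per-gene inverse-dispersions to
#' `<prefix>_beta.tsv` (columns `gene`, `beta`).
#'
#' @param profile a `reference_profile` from [estimate_signatures()].
#' @param prefix path prefix for the two files.
#' @export
write_reference_profile <- function(profile, prefix) {
  du <- data.frame(cell_type = profile$type_order, profile$u,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(du, paste0(prefix, "_u.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  db <- data.frame(gene = profile$gene_ids, beta = profile$beta)
  write.table(db, paste0(prefix, "_beta.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_reference_profile
#' @export
read_reference_profile <- function(prefix) {
  du <- read.delim(paste0(prefix, "_u.tsv"), header = TRUE,
                   check.names = FALSE, stringsAsFactors = FALSE)
  db <- read.delim(paste0(prefix, "_beta.tsv"), header = TRUE,
                   stringsAsFactors = FALSE)
  u <- as.matrix(du[, -1, drop = FALSE])
  rownames(u) <- du[[1]]
  reference_profile(u = u, beta = setNames(db$beta, db$gene),
                    type_order = du[[1]], gene_ids = colnames(u))
}
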