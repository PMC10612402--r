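#' Generate pseudo-spots from a labelled reference
#'
#' A pseudo-spot pools `k ~ Uniform{k_min..k_max}` reference cells drawn
#' uniformly without replacement; its counts are the elementwise sum of the
#' pooled cells' counts and its ground-truth proportions are the cell-count
#' fractions of each type. When `target_umi` is set, the pooled counts are
#' binomially thinned so the expected total UMI matches `target_umi`,
#' putting the supervised training signal in the same noise regime as the
#' low-depth spatial spots being deconvolved.
#'
#' @param reference cells x genes count matrix.
#' @param labels [cell_labels()] aligned with `reference`.
#' @param n_spots number of pseudo-spots.
#' @param cells_per_spot integer range `c(k_min, k_max)`; default `c(1, 5)`
#'   matching the few-cells-per-spot regime of cellular-resolution
#'   platforms.
#' @param target_umi expected total UMI per pseudo-spot after thinning, or
#'   `NULL` for no downsampling. Typically the median total UMI of the
#'   spatial dataset under analysis.
#' @param seed integer seed; the batch is bit-reproducible given the seed.
#' @return list of class `pseudo_spots` with fields `counts` (n_spots x G),
#'   `true_props` (n_spots x T, rows on the simplex), `provenance` (list of
#'   sampled cell ids per spot).
#' @export
generate_pseudo_spots <- function(reference, labels, n_spots,
                                  cells_per_spot = c(1, 5),
                                  target_umi = NULL, seed = 1) {
  stopifnot(n_spots >= 1, length(cells_per_spot) == 2)
  k_min <- as.integer(cells_per_spot[1])
  k_max <- as.integer(cells_per_spot[2])
  if (k_min < 1 || k_max < k_min) {
    stop("cells_per_spot must satisfy 1 <= k_min <= k_max", call. = FALSE)
  }
  if (k_max > nrow(reference)) {
    stop("k_max exceeds the number of reference cells", call. = FALSE)
  }
  if (!identical(rownames(reference), labels$row_ids)) {
    reference <- reference[labels$row_ids, , drop = FALSE]
  }
  types <- labels$type_order
  G <- ncol(reference)

  withr::with_seed(seed, {
    counts <- matrix(0, n_spots, G,
                     dimnames = list(paste0("pseudo", seq_len(n_spots)),
                                     colnames(reference)))
    props <- matrix(0, n_spots, length(types),
                    dimnames = list(rownames(counts), types))
    prov <- vector("list", n_spots)
    ks <- k_min + sample.int(k_max - k_min + 1, n_spots, replace = TRUE) - 1
    for (i in seq_len(n_spots)) {
      cells <- sample.int(nrow(reference), ks[i], replace = FALSE)
      counts[i, ] <- colSums(reference[cells, , drop = FALSE])
      tab <- table(factor(labels$labels[cells], types))
      props[i, ] <- as.numeric(tab) / ks[i]
      prov[[i]] <- labels$row_ids[cells]
    }
    if (!is.null(target_umi)) {
      totals <- rowSums(counts)
      if (all(totals <= target_umi)) {
        warning("target_umi (", target_umi,
                ") is not below any pseudo-spot total; skipping downsampling",
                call. = FALSE)
      } else {
        rate <- pmin(1, target_umi / pmax(totals, 1))
        for (i in seq_len(n_spots)) {
          if (rate[i] < 1) {
            counts[i, ] <- rbinom(G, size = counts[i, ], prob = rate[i])
          }
        }
      }
    }
    structure(list(counts = counts, true_props = props, provenance = prov),
              class = "pseudo_spots")
  })
}

#' @export
print.pseudo_spots <- function(x, ...) {
  cat("pseudo_spots:", nrow(x$counts), "spots x", ncol(x$counts),
      "genes,", ncol(x$true_props), "cell types\n")
  cat("  mean total UMI:", format(mean(rowSums(x$counts)), digits = 4), "\n")
  invisible(x)
}
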