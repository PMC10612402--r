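#' Simulation configuration
#'
#' Defines a fully synthetic study: a labelled single-cell reference drawn
#' from per-type NB signatures, and a spatial tissue laid out on a grid in
#' horizontal bands (one dominant cell type per band, soft borders) that
#' mimics laminar structures such as cortical or olfactory-bulb layers.
#' Spots are shallow — `mean_umi` defaults to 100 total UMI — matching the
#' low-capture regime of cellular-resolution platforms, and compositions
#' are sparse (at most `k_max` cell types per spot).
#'
#' @param n_types number of cell types T (default 5).
#' @param n_genes number of genes G (default 300).
#' @param n_cells_per_type reference cells per type (default 200).
#' @param n_spots number of spatial spots (default 2000).
#' @param grid c(ncol, nrow) spot grid; defaults to an aspect-balanced grid
#'   holding `n_spots`.
#' @param mean_umi mean total UMI per spatial spot (default 100).
#' @param ref_umi mean total UMI per reference cell (default 1000; scRNA-seq
#'   references are sequenced much deeper than spots).
#' @param dispersion_range range for the per-gene NB inverse-dispersion
#'   `beta` (default c(2, 20): clear overdispersion over Poisson).
#' @param k_max maximum distinct cells (hence types) per spot (default 3).
#' @param markers_per_type type-specific upregulated genes (default 10).
#' @param marker_fold marker upregulation factor (default 6; at least the
#'   4-fold needed for markers to be unambiguous at shallow depth).
#' @param softness band-border softness as a fraction of band height
#'   (default 0.5; larger = more mixing at boundaries).
#' @param depth_sd sd of the log-normal per-spot depth factors
#'   (default 0.3), exercising library-size handling downstream.
#' @param seed integer seed; all generators are bit-reproducible from the
#'   config.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_types = 5, n_genes = 300, n_cells_per_type = 200,
                       n_spots = 2000, grid = NULL, mean_umi = 100,
                       ref_umi = 1000, dispersion_range = c(2, 20),
                       k_max = 3, markers_per_type = 10, marker_fold = 6,
                       softness = 0.5, depth_sd = 0.3, seed = 1) {
  if (is.null(grid)) {
    nc <- ceiling(sqrt(n_spots))
    grid <- c(nc, ceiling(n_spots / nc))
  }
  stopifnot(n_types >= 2, n_genes >= n_types * markers_per_type,
            n_cells_per_type >= 2, n_spots >= 1, k_max >= 1,
            mean_umi > 0, ref_umi > 0, marker_fold >= 4,
            prod(grid) >= n_spots)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a labelled single-cell reference
#'
#' Per type `t`, a signature `u_t` is drawn log-normally around a shared
#' per-gene baseline; each type additionally upregulates its own disjoint
#' marker set by `marker_fold`. Cells get log-normal size factors
#' (median-normalized) and counts `x_cg ~ NB(sf_c * u_tg, beta_g)` — the
#' same count model the deconvolution assumes, so estimation can be tested
#' against the exact truth.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (cells x genes), `labels` ([cell_labels()]),
#'   `profile` (the true [reference_profile()]), `markers` (named list of
#'   true marker genes per type).
#' @export
simulate_reference <- function(config) {
  withr::with_seed(config$seed, {
    G <- config$n_genes
    Tt <- config$n_types
    types <- paste0("type", seq_len(Tt))
    genes <- sprintf("g%04d", seq_len(G))
    base <- rlnorm(G, meanlog = 0, sdlog = 1)
    u <- matrix(rep(base, each = Tt), Tt, G,
                dimnames = list(types, genes)) *
      matrix(rlnorm(Tt * G, 0, 0.25), Tt, G)
    markers <- list()
    for (t in seq_len(Tt)) {
      idx <- ((t - 1) * config$markers_per_type + 1):(t * config$markers_per_type)
      u[, idx] <- matrix(rep(base[idx], each = Tt), Tt) # no cross-type noise on markers
      u[t, idx] <- u[t, idx] * config$marker_fold
      markers[[types[t]]] <- genes[idx]
    }
    # scale each signature to the reference depth
    u <- u / rowSums(u) * config$ref_umi
    beta <- runif(G, config$dispersion_range[1], config$dispersion_range[2])

    n <- Tt * config$n_cells_per_type
    lab <- rep(types, each = config$n_cells_per_type)
    sf <- rlnorm(n, 0, config$depth_sd)
    sf <- sf / median(sf)  # u is on the median-library scale
    counts <- matrix(0, n, G,
                     dimnames = list(sprintf("cell%05d", seq_len(n)), genes))
    for (t in seq_len(Tt)) {
      rows <- which(lab == types[t])
      mu <- outer(sf[rows], u[t, ])
      counts[rows, ] <- matrix(
        rnbinom(length(mu), mu = mu, size = per_gene(beta, length(rows), G)),
        length(rows), G)
    }
    list(counts = count_matrix(counts),
         labels = cell_labels(rownames(counts), lab, types),
         profile = reference_profile(u, beta, types, genes),
         markers = markers)
  })
}

#' Simulate a spatial tissue with known ground truth
#'
#' Spots sit on a grid divided into `n_types` horizontal bands with soft
#' borders; each spot pools `k ~ Uniform{1..k_max}` cells whose types are
#' drawn with band-dependent probabilities, so true proportion fields are
#' sparse and spatially autocorrelated (layered, like cortical laminae).
#' Counts follow the generative model `X_ig ~ NB(mu_ig, beta_g)` with
#' `mu_ig = depth_i * sum_t y_it u_tg / sum_g(...)` scaled so the expected
#' total UMI per spot averages `mean_umi` (`s = 1`, `gamma = 0`); per-spot
#' depth factors are log-normal with sd `depth_sd`, normalized to mean 1.
#'
#' @param config a [sim_config()].
#' @param profile a [reference_profile()] (e.g. the truth from
#'   [simulate_reference()]).
#' @return list with `counts` (spots x genes), `coords` ([spot_coords()]),
#'   `props` (true N x T proportions).
#' @export
simulate_tissue <- function(config, profile) {
  withr::with_seed(config$seed + 1L, {
    N <- config$n_spots
    Tt <- length(profile$type_order)
    G <- length(profile$gene_ids)
    nc <- config$grid[1]
    xs <- ((seq_len(N) - 1) %% nc) + 1
    ys <- ((seq_len(N) - 1) %/% nc) + 1
    ids <- sprintf("spot%05d", seq_len(N))
    coords <- spot_coords(ids, cbind(xs, ys))

    # band-dependent type probabilities: Gaussian bump around each band
    # centre plus a small uniform floor for boundary mixing
    ymax <- max(ys)
    centers <- (seq_len(Tt) - 0.5) / Tt
    width <- config$softness / Tt
    yfrac <- (ys - 0.5) / ymax
    w <- sapply(centers, function(cc) exp(-((yfrac - cc) / width)^2 / 2))
    w <- w + 0.02
    w <- w / rowSums(w)

    ks <- sample.int(config$k_max, N, replace = TRUE)
    props <- matrix(0, N, Tt, dimnames = list(ids, profile$type_order))
    for (i in seq_len(N)) {
      cells <- sample.int(Tt, ks[i], replace = TRUE, prob = w[i, ])
      props[i, ] <- tabulate(cells, Tt) / ks[i]
    }

    depth <- rlnorm(N, 0, config$depth_sd)
    depth <- depth / mean(depth) * config$mean_umi
    Mu <- props %*% profile$u
    Mu <- Mu / rowSums(Mu) * depth  # expected total = depth_i
    counts <- matrix(
      rnbinom(length(Mu), mu = Mu, size = per_gene(profile$beta, N, G)),
      N, G, dimnames = list(ids, profile$gene_ids))
    list(counts = count_matrix(counts), coords = coords, props = props)
  })
}
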