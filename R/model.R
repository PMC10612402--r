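#' Construct the variational deconvolution model
#'
#' The generative model: a latent code `Z_i ~ N(0, I)` is decoded into a
#' cell-type proportion vector `Y_i` (hidden ReLU stack, linear layer to T
#' logits, sparsemax), and the observed counts follow
#' `X_ig ~ NB(mu_ig, beta_g)` with
#' `mu_ig = l_i * (s_g * sum_t y_it u_tg + gamma_g)`,
#' where `u` (cell-type signatures) and `beta` (gene inverse-dispersions)
#' come frozen from the reference profile, `s_g` is a trainable
#' gene-specific scaling, `gamma_g` a trainable gene-specific additive
#' noise, and `l_i` an optional fixed per-spot size factor (total count /
#' median total count). The encoder (ReLU stack with linear heads for the
#' posterior mean and log-variance) amortizes inference of `Z_i` from the
#' `log1p`-transformed counts.
#'
#' @param profile a `reference_profile` providing `u`, `beta`, gene ids and
#'   type order.
#' @param latent_dim latent dimension D (default 10).
#' @param hidden hidden layer widths shared by encoder and decoder
#'   (default `c(128, 128)`).
#' @param likelihood `"nb"`, `"poisson"` or `"zinb"` observation model.
#' @param use_size_factor multiply `mu` by per-spot total / median total
#'   (default TRUE); switch off for data of uniform depth.
#' @param s_init initial value for all `s_g`; default 1. During training
#'   `s` is re-initialized to the ratio of spot depth to signature depth so
#'   the likelihood starts on scale.
#' @param seed seed for parameter initialization.
#' @return list of class `spotsparse_model`.
#' @export
variational_model <- function(profile, latent_dim = 10,
                              hidden = c(128, 128),
                              likelihood = c("nb", "poisson", "zinb"),
                              use_size_factor = TRUE, s_init = 1,
                              seed = 1) {
  likelihood <- match.arg(likelihood)
  stopifnot(inherits(profile, "reference_profile"), latent_dim >= 1)
  G <- length(profile$gene_ids)
  Tt <- length(profile$type_order)
  par <- withr::with_seed(seed, init_model_params(
    G, Tt, latent_dim, hidden, likelihood, s_init))
  structure(list(
    par = par,
    u = profile$u,
    beta = profile$beta,
    gene_ids = profile$gene_ids,
    type_order = profile$type_order,
    latent_dim = latent_dim,
    hidden = hidden,
    likelihood = likelihood,
    use_size_factor = use_size_factor,
    sigma_floor = 1e-4,
    ref_depth = NULL,
    seed = seed
  ), class = "spotsparse_model")
}

init_model_params <- function(G, Tt, D, hidden, likelihood, s_init) {
  par <- c(init_stack("enc", c(G, hidden)),
           list(enc_Wm = init_dense(hidden[length(hidden)], D)$W,
                enc_bm = numeric(D),
                enc_Wv = init_dense(hidden[length(hidden)], D)$W,
                enc_bv = numeric(D)),
           init_stack("dec", c(D, hidden)),
           list(dec_Wo = init_dense(hidden[length(hidden)], Tt)$W,
                dec_bo = numeric(Tt),
                log_s = rep(log(s_init), G),
                # softplus^{-1}(0.01): start gamma near zero but positive
                gamma_raw = rep(log(expm1(0.01)), G)))
  if (likelihood == "zinb") par$tau_raw <- rep(-3, G)
  par
}

#' @export
print.spotsparse_model <- function(x, ...) {
  cat("spotsparse_model:", length(x$gene_ids), "genes,",
      length(x$type_order), "cell types, latent dim", x$latent_dim, "\n")
  cat("  likelihood:", x$likelihood, " hidden:",
      paste(x$hidden, collapse = "-"), "\n")
  invisible(x)
}

check_genes <- function(model, X) {
  if (ncol(X) != length(model$gene_ids)) {
    stop(sprintf("gene dimension mismatch: data has %d genes, model %d",
                 ncol(X), length(model$gene_ids)), call. = FALSE)
  }
  if (!is.null(colnames(X)) && !identical(colnames(X), model$gene_ids)) {
    if (setequal(colnames(X), model$gene_ids)) {
      return(X[, model$gene_ids, drop = FALSE])
    }
    stop("gene identifiers do not match the model's gene space",
         call. = FALSE)
  }
  X
}

#' Encode counts into the variational posterior
#'
#' @param model a `spotsparse_model`.
#' @param X spots x genes count matrix in the model's gene space.
#' @return list with `mu_z` (N x D posterior means) and `sigma_z` (N x D
#'   posterior standard deviations, floored at the model's sigma floor).
#' @export
encode <- function(model, X) {
  X <- check_genes(model, X)
  fw <- encoder_fwd(model$par, log1p(X), length(model$hidden),
                    model$sigma_floor)
  list(mu_z = fw$mu, sigma_z = fw$sigma)
}

encoder_fwd <- function(par, H0, n_layers, sigma_floor) {
  st <- stack_fwd(par, "enc", H0, n_layers)
  mu <- dense_fwd(st$H, par$enc_Wm, par$enc_bm)
  logvar <- dense_fwd(st$H, par$enc_Wv, par$enc_bv)
  sigma_raw <- exp(0.5 * logvar)
  list(mu = mu, logvar = logvar, sigma = pmax(sigma_raw, sigma_floor),
       sigma_raw = sigma_raw, stack = st)
}

#' Reparameterized sampling of the latent code
#'
#' `Z = mu_z + sigma_z * z_std` with `z_std` i.i.d. standard normal, so
#' gradients flow through the sampling step.
#'
#' @param enc output of [encode()].
#' @param seed optional integer; when given, draws come from a local RNG
#'   seeded with it (the ambient RNG state is untouched).
#' @return list with `z_std` (the standard-normal draws) and `z` (the
#'   reparameterized samples).
#' @export
reparameterize <- function(enc, seed = NULL) {
  draw <- function() {
    matrix(rnorm(length(enc$mu_z)), nrow(enc$mu_z), ncol(enc$mu_z))
  }
  eps <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  list(z_std = eps, z = enc$mu_z + enc$sigma_z * eps)
}

#' Decode latent codes into cell-type proportions
#'
#' Hidden ReLU stack, linear logits, row-wise sparsemax; deterministic
#' given `Z`, rows exactly on the simplex with exact zeros allowed.
#'
#' @param model a `spotsparse_model`.
#' @param Z an N x D matrix of latent codes, or the output of
#'   [reparameterize()].
#' @return N x T proportion matrix (columns named by cell type).
#' @export
decode <- function(model, Z) {
  if (is.list(Z)) Z <- Z$z
  if (ncol(Z) != model$latent_dim) {
    stop(sprintf("latent dimension mismatch: got %d, model has %d",
                 ncol(Z), model$latent_dim), call. = FALSE)
  }
  st <- stack_fwd(model$par, "dec", Z, length(model$hidden))
  logits <- dense_fwd(st$H, model$par$dec_Wo, model$par$dec_bo)
  Y <- sparsemax_rows(logits)
  colnames(Y) <- model$type_order
  Y
}

#' Expected expression under the mixing model
#'
#' `mu_ig = library_i * (s_g * sum_t y_it u_tg + gamma_g)`.
#'
#' @param Y N x T proportion matrix (rows on the simplex).
#' @param profile a `reference_profile` (provides `u`).
#' @param s per-gene positive scaling (scalar or length G; default 1).
#' @param gamma per-gene non-negative additive noise (scalar or length G;
#'   default 0).
#' @param library per-spot size factor (scalar or length N; default 1).
#' @return N x G matrix of non-negative expected expression.
#' @export
expected_expression <- function(Y, profile, s = 1, gamma = 0, library = 1) {
  validate_proportions(Y)
  if (any(s <= 0)) stop("s must be positive", call. = FALSE)
  if (any(gamma < 0)) stop("gamma must be non-negative", call. = FALSE)
  u <- profile$u
  if (ncol(Y) != nrow(u)) {
    stop("proportion columns must match the profile's cell types",
         call. = FALSE)
  }
  M <- Y %*% u
  G <- ncol(M)
  n <- nrow(M)
  S <- if (length(s) == 1) s else per_gene(s, n, G)
  Gm <- if (length(gamma) == 1) gamma else per_gene(gamma, n, G)
  library * (M * S + Gm)
}

#' Per-spot log-likelihood of counts
#'
#' Sums the configured log pmf (`nb`, `poisson` or `zinb`) over genes for
#' each spot; `beta` comes frozen from the model's reference profile and
#' `tau` (zinb only) from the model parameters.
#'
#' @param X spots x genes counts.
#' @param mu matching matrix of expected expression.
#' @param model a `spotsparse_model`.
#' @return length-N vector of per-spot log-likelihoods (finite for valid
#'   inputs; `mu` is floored internally).
#' @export
count_log_likelihood <- function(X, mu, model) {
  if (any(X < 0)) stop("counts must be non-negative", call. = FALSE)
  if (!all(dim(X) == dim(mu))) stop("X and mu shapes differ", call. = FALSE)
  ll <- switch(model$likelihood,
    nb = nb_log_pmf(X, mu, model$beta),
    poisson = poisson_log_pmf(X, mu),
    zinb = zinb_log_pmf(X, mu, model$beta, sigmoid(model$par$tau_raw))
  )
  rowSums(ll)
}

#' Feed-forward ablation model (no latent sampling)
#'
#' The same hidden stack and sparsemax output layer as the decoder, but
#' applied directly to `log1p` counts: a deterministic map from expression
#' to the simplex, trainable with the supervised pseudo-spot loss alone.
#'
#' @param profile a `reference_profile` (fixes genes and type order).
#' @param hidden hidden widths (default `c(128, 128)`).
#' @param seed initialization seed.
#' @return list of class `spotsparse_dnn`.
#' @export
dnn_model <- function(profile, hidden = c(128, 128), seed = 1) {
  G <- length(profile$gene_ids)
  Tt <- length(profile$type_order)
  par <- withr::with_seed(seed, c(
    init_stack("dnn", c(G, hidden)),
    list(dnn_Wo = init_dense(hidden[length(hidden)], Tt)$W,
         dnn_bo = numeric(Tt))))
  structure(list(par = par, gene_ids = profile$gene_ids,
                 type_order = profile$type_order, hidden = hidden),
            class = "spotsparse_dnn")
}

#' @rdname dnn_model
#' @param dnn a `spotsparse_dnn`.
#' @param X spots x genes counts.
#' @return N x T proportion matrix.
#' @export
dnn_forward <- function(dnn, X) {
  if (ncol(X) != length(dnn$gene_ids)) {
    stop("gene dimension mismatch", call. = FALSE)
  }
  st <- stack_fwd(dnn$par, "dnn", log1p(X), length(dnn$hidden))
  logits <- dense_fwd(st$H, dnn$par$dnn_Wo, dnn$par$dnn_bo)
  Y <- sparsemax_rows(logits)
  colnames(Y) <- dnn$type_order
  Y
}

#' Save / load a model checkpoint
#'
#' A single serialized file holding all parameters plus the configuration
#' (gene list, type order, likelihood, architecture), so inference is
#' self-describing.
#'
#' @param model a `spotsparse_model`.
#' @param path checkpoint file.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "spotsparse_model"))
  m
}
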