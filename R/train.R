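#' Training configuration
#'
#' @param batch_size mini-batch size (default 128).
#' @param epochs training epochs (default 100).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param kl_weight weight on the KL term (default 1).
#' @param supervised_weight weight on the pseudo-spot L1 term (default 1).
#' @param pseudo_ratio fraction of each mini-batch drawn from pseudo-spots
#'   (default 0.5; ignored when no pseudo-spots are supplied).
#' @param seed single seed governing initialization, batch shuffling and
#'   reparameterization draws.
#' @param val_fraction fraction of pseudo-spots held out to monitor
#'   validation loss (default 0.1).
#' @param patience early-stopping patience in epochs (default 10).
#' @param pretrain_epochs optional supervised-only warm-up epochs on
#'   pseudo-spots before joint training (default 0 = joint from the start).
#' @param clip global gradient-norm clip (default 10).
#' @param reinit re-initialize model parameters from `seed` at the start of
#'   training (default TRUE); set FALSE to continue training a model.
#' @param verbose print per-epoch losses.
#' @return list of class `training_config`.
#' @export
training_config <- function(batch_size = 128, epochs = 100,
                            learning_rate = 1e-3, kl_weight = 1,
                            supervised_weight = 1, pseudo_ratio = 0.5,
                            seed = 1, val_fraction = 0.1, patience = 10,
                            pretrain_epochs = 0, clip = 10, reinit = TRUE,
                            verbose = FALSE) {
  stopifnot(batch_size >= 1, epochs >= 0, learning_rate > 0,
            kl_weight >= 0, supervised_weight >= 0,
            pseudo_ratio >= 0, pseudo_ratio <= 1)
  structure(as.list(environment()), class = "training_config")
}

#' KL divergence of a diagonal Gaussian from the standard normal
#'
#' Closed form per spot: `sum_d 0.5 * (mu_d^2 + sigma_d^2 - 1 -
#' log sigma_d^2)`; always non-negative, zero iff the posterior equals the
#' prior.
#'
#' @param enc output of [encode()] (fields `mu_z`, `sigma_z`).
#' @return length-N non-negative vector.
#' @export
kl_standard_normal <- function(enc) {
  if (any(enc$sigma_z <= 0)) stop("sigma_z must be positive", call. = FALSE)
  s2 <- enc$sigma_z^2
  rowSums(0.5 * (enc$mu_z^2 + s2 - 1 - log(s2)))
}

#' Supervised loss on proportions
#'
#' Mean per-spot L1 distance `sum_t |y_pred - y_true| / N`; zero iff equal,
#' symmetric, bounded by 2. L1 is safe with sparsemax outputs (exact zeros
#' off-support), unlike cross-entropy.
#'
#' @param pred,truth N x T proportion matrices (rows on the simplex).
#' @return non-negative scalar.
#' @export
supervised_loss <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) {
    stop("prediction and truth shapes differ", call. = FALSE)
  }
  validate_proportions(pred)
  validate_proportions(truth)
  sum(abs(pred - truth)) / nrow(pred)
}

# per-spot size factors relative to the model's reference depth
spot_size_factors <- function(model, X) {
  if (!isTRUE(model$use_size_factor)) return(rep(1, nrow(X)))
  totals <- rowSums(X)
  depth <- model$ref_depth
  if (is.null(depth) || !is.finite(depth) || depth <= 0) {
    depth <- median(totals)
  }
  if (depth <= 0) return(rep(1, nrow(X)))
  totals / depth
}

#' Monte-Carlo ELBO components for a batch
#'
#' Runs encode -> reparameterize -> decode -> expected expression ->
#' count log-likelihood with a single latent sample per spot and returns
#' the batch-mean reconstruction and KL terms of the objective
#' (`recon = -E_q[log p(X|Z)]`, `kl = D_KL(q || N(0, I))`).
#'
#' @param model a `spotsparse_model`.
#' @param X spots x genes counts.
#' @param seed seed for the latent draws.
#' @return list with `recon`, `kl` and `total = recon + kl`.
#' @export
elbo_loss <- function(model, X, seed = 1) {
  X <- check_genes(model, X)
  enc <- encode(model, X)
  lat <- reparameterize(enc, seed = seed)
  Y <- decode(model, lat$z)
  s <- exp(model$par$log_s)
  gam <- softplus(model$par$gamma_raw)
  lib <- spot_size_factors(model, X)
  prof <- reference_profile(model$u, model$beta, model$type_order,
                            model$gene_ids)
  mu <- expected_expression(Y, prof, s = s, gamma = gam, library = lib)
  recon <- -mean(count_log_likelihood(X, mu, model))
  kl <- mean(kl_standard_normal(enc))
  list(recon = recon, kl = kl, total = recon + kl)
}

# ---------------------------------------------------------------------
# fused forward/backward pass for one mini-batch
#
# sup_rows: logical marking pseudo-spot rows; Ytrue has one row per TRUE.
# Returns loss components and gradients for every trainable parameter
# (phi, omega, log_s, gamma_raw[, tau_raw]); u and beta stay frozen.
loss_grad <- function(par, model, Xb, lib, eps, sup_rows = NULL,
                      Ytrue = NULL, kl_weight = 1, supervised_weight = 1,
                      recon_weight = 1) {
  n <- nrow(Xb)
  G <- ncol(Xb)
  L <- length(model$hidden)
  u <- model$u
  beta <- model$beta
  B <- per_gene(beta, n, G)

  enc <- encoder_fwd(par, log1p(Xb), L, model$sigma_floor)
  Z <- enc$mu + enc$sigma * eps
  dst <- stack_fwd(par, "dec", Z, L)
  logits <- dense_fwd(dst$H, par$dec_Wo, par$dec_bo)
  Y <- sparsemax_rows(logits)

  s <- exp(par$log_s)
  gam <- softplus(par$gamma_raw)
  S <- per_gene(s, n, G)
  Gm <- per_gene(gam, n, G)
  M <- Y %*% u
  mu_raw <- lib * (M * S + Gm)
  mu <- pmax(mu_raw, MU_FLOOR)
  live <- mu_raw > MU_FLOOR

  if (model$likelihood == "zinb") {
    tau <- sigmoid(par$tau_raw)
    Tau <- per_gene(tau, n, G)
    llm <- zinb_log_pmf(Xb, mu, B, Tau)
  } else if (model$likelihood == "poisson") {
    llm <- poisson_log_pmf(Xb, mu)
  } else {
    llm <- nb_log_pmf(Xb, mu, B)
  }
  recon <- -sum(llm) / n
  s2 <- exp(enc$logvar)
  klv <- rowSums(0.5 * (enc$mu^2 + s2 - 1 - enc$logvar))
  kl <- mean(klv)
  sup <- 0
  n_sup <- if (is.null(sup_rows)) 0 else sum(sup_rows)
  if (n_sup > 0) {
    diffs <- Y[sup_rows, , drop = FALSE] - Ytrue
    sup <- sum(abs(diffs)) / n_sup
  }
  total <- recon_weight * recon + kl_weight * kl + supervised_weight * sup

  # ---- backward ----
  dll <- switch(model$likelihood,
    nb = nb_dll_dmu(Xb, mu, B),
    poisson = Xb / mu - 1,
    zinb = {
      zero <- Xb == 0
      d <- nb_dll_dmu(Xb, mu, B)
      p0 <- exp(B * (log(B) - log(B + mu)))
      dz <- (1 - Tau) * (-p0 * B / (B + mu)) / (Tau + (1 - Tau) * p0)
      d[zero] <- dz[zero]
      d
    })
  dmu <- (-recon_weight / n) * dll * live
  dM <- dmu * lib * S
  g_log_s <- colSums(dmu * lib * M) * s
  g_gamma <- colSums(dmu * lib) * sigmoid(par$gamma_raw)
  dY <- dM %*% t(u)
  if (n_sup > 0) {
    dY[sup_rows, ] <- dY[sup_rows, ] +
      (supervised_weight / n_sup) * sign(diffs)
  }
  dlogits <- sparsemax_backward(Y, dY)
  grads <- list(dec_Wo = crossprod(dst$H, dlogits),
                dec_bo = colSums(dlogits),
                log_s = g_log_s, gamma_raw = g_gamma)
  if (model$likelihood == "zinb") {
    zero <- Xb == 0
    p0 <- exp(B * (log(B) - log(B + mu)))
    dtau <- ifelse(zero, (1 - p0) / (Tau + (1 - Tau) * p0), -1 / (1 - Tau))
    grads$tau_raw <- colSums((-recon_weight / n) * dtau) * tau * (1 - tau)
  }
  dec_bw <- stack_bwd(par, "dec", dst$cache, tcrossprod(dlogits, par$dec_Wo))
  grads <- add_grads(grads, dec_bw$grads)
  dZ <- dec_bw$dX
  dmu_z <- dZ + (kl_weight / n) * enc$mu
  dsig <- dZ * eps
  sig_live <- enc$sigma_raw > model$sigma_floor
  dlogvar <- dsig * 0.5 * enc$sigma_raw * sig_live +
    (kl_weight / n) * 0.5 * (s2 - 1)
  grads$enc_Wm <- crossprod(enc$stack$H, dmu_z)
  grads$enc_bm <- colSums(dmu_z)
  grads$enc_Wv <- crossprod(enc$stack$H, dlogvar)
  grads$enc_bv <- colSums(dlogvar)
  dH <- tcrossprod(dmu_z, par$enc_Wm) + tcrossprod(dlogvar, par$enc_Wv)
  enc_bw <- stack_bwd(par, "enc", enc$stack$cache, dH)
  grads <- add_grads(grads, enc_bw$grads)

  list(total = total, recon = recon, kl = kl, supervised = sup,
       grads = grads, Y = Y)
}

#' Train the deconvolution model
#'
#' Mini-batches mix real spatial spots (reconstruction + KL terms) with
#' pseudo-spots (same terms plus the supervised L1 on their known
#' proportions). Trainable parameters are the encoder, the decoder and the
#' gene-specific `s`/`gamma` (and `tau` for zinb); the signatures `u` and
#' dispersions `beta` stay frozen at their reference estimates. A 10%
#' validation split of the pseudo-spots drives early stopping (patience in
#' `config`); the best-validation parameters are restored. Fully
#' reproducible from `config$seed`.
#'
#' @param model a `spotsparse_model`.
#' @param spatial spots x genes counts in the model's gene space.
#' @param pseudo optional `pseudo_spots` batch (same gene space).
#' @param config a [training_config()].
#' @return list of class `spotsparse_fit`: `model` (trained), `history`
#'   (tibble of per-epoch loss components), `best_epoch`.
#' @export
train <- function(model, spatial, pseudo = NULL,
                  config = training_config()) {
  if (nrow(spatial) == 0) stop("spatial data is empty", call. = FALSE)
  spatial <- check_genes(model, spatial)
  if (config$epochs == 0 && config$pretrain_epochs == 0) {
    return(structure(list(model = model, history = empty_history(),
                          best_epoch = 0L), class = "spotsparse_fit"))
  }
  set.seed(config$seed)
  model$ref_depth <- median(rowSums(spatial))
  if (isTRUE(config$reinit)) {
    # re-initialize networks; put s on the depth scale of the data so the
    # likelihood starts near the right order of magnitude
    sig_depth <- mean(rowSums(model$u))
    s0 <- max(model$ref_depth, 1) / max(sig_depth, 1e-8)
    model$par <- init_model_params(length(model$gene_ids),
                                   length(model$type_order),
                                   model$latent_dim, model$hidden,
                                   model$likelihood, s_init = s0)
  }
  lib_real <- spot_size_factors(model, spatial)

  has_pseudo <- !is.null(pseudo) && nrow(pseudo$counts) > 0
  if (has_pseudo) {
    Xp <- check_genes(model, pseudo$counts)
    Yp <- pseudo$true_props[, model$type_order, drop = FALSE]
    lib_ps <- spot_size_factors(model, Xp)
    n_ps <- nrow(Xp)
    n_val <- floor(config$val_fraction * n_ps)
    val_idx <- if (n_val > 0) sample.int(n_ps, n_val) else integer(0)
    tr_idx <- setdiff(seq_len(n_ps), val_idx)
  } else {
    tr_idx <- integer(0)
  }

  par <- model$par
  state <- adam_init(par)
  n_real <- nrow(spatial)
  n_ps_batch <- if (has_pseudo) {
    max(1, round(config$batch_size * config$pseudo_ratio))
  } else 0
  n_real_batch <- max(1, config$batch_size - n_ps_batch)

  hist <- list()
  best <- list(val = Inf, par = par, epoch = 0L)
  wait <- 0

  # optional supervised-only warm-up on pseudo-spots
  if (config$pretrain_epochs > 0 && has_pseudo) {
    for (ep in seq_len(config$pretrain_epochs)) {
      ord <- tr_idx[sample.int(length(tr_idx))]
      for (b in split_batches(ord, config$batch_size)) {
        eps <- matrix(rnorm(length(b) * model$latent_dim), length(b))
        lg <- loss_grad(par, model, Xp[b, , drop = FALSE], lib_ps[b], eps,
                        sup_rows = rep(TRUE, length(b)),
                        Ytrue = Yp[b, , drop = FALSE],
                        kl_weight = 0, recon_weight = 0,
                        supervised_weight = config$supervised_weight)
        upd <- adam_step(par, clip_grads(lg$grads, config$clip), state,
                         config$learning_rate)
        par <- upd$par
        state <- upd$state
      }
    }
  }

  epoch <- 0L
  while (epoch < config$epochs) {
    epoch <- epoch + 1L
    ord_real <- sample.int(n_real)
    if (has_pseudo && length(tr_idx) > 0) {
      ps_pool <- tr_idx[sample.int(length(tr_idx))]
    }
    ps_ptr <- 0
    acc <- c(total = 0, recon = 0, kl = 0, supervised = 0)
    nb <- 0
    for (b in split_batches(ord_real, n_real_batch)) {
      if (has_pseudo && length(tr_idx) > 0) {
        take <- min(n_ps_batch, length(tr_idx))
        pick <- integer(take)
        for (j in seq_len(take)) {
          ps_ptr <- ps_ptr + 1
          if (ps_ptr > length(ps_pool)) {
            ps_pool <- tr_idx[sample.int(length(tr_idx))]
            ps_ptr <- 1
          }
          pick[j] <- ps_pool[ps_ptr]
        }
        Xb <- rbind(spatial[b, , drop = FALSE], Xp[pick, , drop = FALSE])
        lib <- c(lib_real[b], lib_ps[pick])
        sup_rows <- c(rep(FALSE, length(b)), rep(TRUE, take))
        Ytrue <- Yp[pick, , drop = FALSE]
      } else {
        Xb <- spatial[b, , drop = FALSE]
        lib <- lib_real[b]
        sup_rows <- NULL
        Ytrue <- NULL
      }
      eps <- matrix(rnorm(nrow(Xb) * model$latent_dim), nrow(Xb))
      lg <- loss_grad(par, model, Xb, lib, eps, sup_rows, Ytrue,
                      kl_weight = config$kl_weight,
                      supervised_weight = config$supervised_weight)
      if (!is.finite(lg$total)) {
        stop(sprintf("NaN/Inf loss at epoch %d, batch %d", epoch, nb + 1),
             call. = FALSE)
      }
      upd <- adam_step(par, clip_grads(lg$grads, config$clip), state,
                       config$learning_rate)
      par <- upd$par
      state <- upd$state
      acc <- acc + c(lg$total, lg$recon, lg$kl, lg$supervised)
      nb <- nb + 1
    }
    acc <- acc / nb

    val <- NA_real_
    if (has_pseudo && length(val_idx) > 0) {
      eps0 <- matrix(0, length(val_idx), model$latent_dim)
      vl <- loss_grad(par, model, Xp[val_idx, , drop = FALSE],
                      lib_ps[val_idx], eps0,
                      sup_rows = rep(TRUE, length(val_idx)),
                      Ytrue = Yp[val_idx, , drop = FALSE],
                      kl_weight = config$kl_weight,
                      supervised_weight = config$supervised_weight)
      val <- vl$total
    }
    hist[[epoch]] <- c(epoch = epoch, acc, val_total = val)
    if (config$verbose) {
      message(sprintf("epoch %3d  total %.4f  recon %.4f  kl %.4f  sup %.4f%s",
                      epoch, acc["total"], acc["recon"], acc["kl"],
                      acc["supervised"],
                      if (is.na(val)) "" else sprintf("  val %.4f", val)))
    }
    monitor <- if (is.na(val)) acc[["total"]] else val
    if (monitor < best$val - 1e-8) {
      best <- list(val = monitor, par = par, epoch = epoch)
      wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= config$patience) break
    }
  }

  model$par <- best$par
  history <- as_tibble(do.call(rbind, hist))
  structure(list(model = model, history = history,
                 best_epoch = best$epoch),
            class = "spotsparse_fit")
}

split_batches <- function(ord, size) {
  split(ord, ceiling(seq_along(ord) / size))
}

empty_history <- function() {
  tibble(epoch = integer(), total = numeric(), recon = numeric(),
         kl = numeric(), supervised = numeric(), val_total = numeric())
}

#' @export
print.spotsparse_fit <- function(x, ...) {
  cat("spotsparse_fit:", nrow(x$history), "epochs trained (best epoch",
      x$best_epoch, ")\n")
  if (nrow(x$history) > 0) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final losses: total %.4f recon %.4f kl %.4f sup %.4f\n",
                last$total, last$recon, last$kl, last$supervised))
  }
  invisible(x)
}

#' Deconvolve spatial spots into cell-type proportions
#'
#' Inference is deterministic: the posterior mean `Z = E_mu(X)` (no
#' sampling) is pushed through the decoder. Spots are processed in batches
#' to bound memory.
#'
#' @param model a trained `spotsparse_model` or a `spotsparse_fit`.
#' @param spatial spots x genes counts in the model's gene space.
#' @param batch_size spots per inference batch (default 1024).
#' @return N x T proportion matrix (rows on the simplex, spot ids as
#'   rownames, cell types as colnames).
#' @export
deconvolve <- function(model, spatial, batch_size = 1024) {
  if (inherits(model, "spotsparse_fit")) model <- model$model
  spatial <- check_genes(model, spatial)
  out <- matrix(0, nrow(spatial), length(model$type_order),
                dimnames = list(rownames(spatial), model$type_order))
  for (b in split_batches(seq_len(nrow(spatial)), batch_size)) {
    enc <- encode(model, spatial[b, , drop = FALSE])
    out[b, ] <- decode(model, enc$mu_z)
  }
  out
}

#' Train the feed-forward ablation on pseudo-spots
#'
#' Supervised L1 loss only (no reconstruction, no KL): the ablation used to
#' check what the latent generative model adds over a plain regression from
#' counts to compositions.
#'
#' @param dnn a [dnn_model()].
#' @param pseudo a `pseudo_spots` batch.
#' @param config a [training_config()] (only batch_size, epochs,
#'   learning_rate, seed, clip are used).
#' @return list of class `spotsparse_dnn_fit` with `dnn` and `history`.
#' @export
train_dnn <- function(dnn, pseudo, config = training_config()) {
  Xp <- pseudo$counts
  Yp <- pseudo$true_props[, dnn$type_order, drop = FALSE]
  set.seed(config$seed)
  par <- dnn$par
  state <- adam_init(par)
  L <- length(dnn$hidden)
  hist <- numeric(0)
  for (ep in seq_len(config$epochs)) {
    tot <- 0
    nb <- 0
    for (b in split_batches(sample.int(nrow(Xp)), config$batch_size)) {
      st <- stack_fwd(par, "dnn", log1p(Xp[b, , drop = FALSE]), L)
      logits <- dense_fwd(st$H, par$dnn_Wo, par$dnn_bo)
      Y <- sparsemax_rows(logits)
      diffs <- Y - Yp[b, , drop = FALSE]
      loss <- sum(abs(diffs)) / length(b)
      dY <- sign(diffs) / length(b)
      dlogits <- sparsemax_backward(Y, dY)
      grads <- list(dnn_Wo = crossprod(st$H, dlogits),
                    dnn_bo = colSums(dlogits))
      bw <- stack_bwd(par, "dnn", st$cache, tcrossprod(dlogits, par$dnn_Wo))
      grads <- add_grads(grads, bw$grads)
      upd <- adam_step(par, clip_grads(grads, config$clip), state,
                       config$learning_rate)
      par <- upd$par
      state <- upd$state
      tot <- tot + loss
      nb <- nb + 1
    }
    hist <- c(hist, tot / nb)
  }
  dnn$par <- par
  structure(list(dnn = dnn,
                 history = tibble(epoch = seq_along(hist),
                                  supervised = hist)),
            class = "spotsparse_dnn_fit")
}
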