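# Minimal feed-forward network machinery (dense layers, ReLU, Adam).
# Parameters live in a flat named list of matrices/vectors so the optimizer
# and serialization can traverse them generically; gradients mirror the
# structure. All randomness goes through R's RNG stream so a single seed
# makes training reproducible.

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
sigmoid <- function(x) 1 / (1 + exp(-x))
relu <- function(x) pmax(x, 0)

# He-normal initialization for one dense layer
init_dense <- function(n_in, n_out, scale = sqrt(2 / n_in)) {
  list(W = matrix(rnorm(n_in * n_out, sd = scale), n_in, n_out),
       b = numeric(n_out))
}

# stack of hidden layers prefix_W1/b1, ..., prefix_WL/bL (ReLU between)
init_stack <- function(prefix, dims) {
  par <- list()
  for (l in seq_len(length(dims) - 1)) {
    d <- init_dense(dims[l], dims[l + 1])
    par[[paste0(prefix, "_W", l)]] <- d$W
    par[[paste0(prefix, "_b", l)]] <- d$b
  }
  par
}

dense_fwd <- function(X, W, b) sweep(X %*% W, 2, b, "+")

# forward through a ReLU stack; returns final activation and layer cache
stack_fwd <- function(par, prefix, X, n_layers) {
  H <- X
  cache <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    A <- dense_fwd(H, par[[paste0(prefix, "_W", l)]],
                   par[[paste0(prefix, "_b", l)]])
    cache[[l]] <- list(input = H, pre = A)
    H <- relu(A)
  }
  list(H = H, cache = cache)
}

# backward through the stack; dH is gradient w.r.t. the stack output
stack_bwd <- function(par, prefix, cache, dH) {
  grads <- list()
  for (l in rev(seq_along(cache))) {
    dA <- dH * (cache[[l]]$pre > 0)
    grads[[paste0(prefix, "_W", l)]] <- crossprod(cache[[l]]$input, dA)
    grads[[paste0(prefix, "_b", l)]] <- colSums(dA)
    dH <- tcrossprod(dA, par[[paste0(prefix, "_W", l)]])
  }
  list(grads = grads, dX = dH)
}

# --- Adam -------------------------------------------------------------

adam_init <- function(par) {
  list(m = lapply(par, function(p) p * 0),
       v = lapply(par, function(p) p * 0),
       t = 0)
}

adam_step <- function(par, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(par)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    par[[nm]] <- par[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(par = par, state = state)
}

# global gradient-norm clipping (standard stabilizer for count likelihoods
# whose x/mu terms can spike early in training)
clip_grads <- function(grads, max_norm) {
  nrm <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
  if (is.finite(nrm) && nrm > max_norm) {
    grads <- lapply(grads, function(g) g * (max_norm / nrm))
  }
  grads
}

# elementwise sum of two gradient lists (union of names)
add_grads <- function(a, b) {
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}
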