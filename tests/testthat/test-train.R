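toy_one_gene_model <- function() {
  # 1 gene, 1 type, u = 1, beta = 1, s = 1, gamma = 0, no size factors:
  # with T = 1 the sparsemax output is forced to y = 1
  prof <- reference_profile(matrix(1, 1, 1, dimnames = list("t1", "g1")),
                            beta = 1)
  m <- variational_model(prof, latent_dim = 2, hidden = c(4, 4),
                         use_size_factor = FALSE, seed = 5)
  m$par$log_s[] <- 0
  m$par$gamma_raw[] <- -Inf  # softplus(-Inf) = 0
  m
}

test_that("the closed-form KL matches hand values and quadrature", {
  enc <- list(mu_z = matrix(0, 2, 3), sigma_z = matrix(1, 2, 3))
  expect_equal(kl_standard_normal(enc), c(0, 0))
  enc1 <- list(mu_z = matrix(1, 1, 1), sigma_z = matrix(1, 1, 1))
  expect_equal(kl_standard_normal(enc1), 0.5)
  set.seed(14)
  for (i in 1:5) {
    mu <- rnorm(3)
    sig <- runif(3, 0.3, 2)
    enc <- list(mu_z = matrix(mu, 1), sigma_z = matrix(sig, 1))
    expect_equal(kl_standard_normal(enc), kl_quadrature(mu, sig),
                 tolerance = 1e-4)
  }
  expect_true(all(kl_standard_normal(list(
    mu_z = matrix(rnorm(20), 5), sigma_z = matrix(runif(20, 0.1, 3), 5)))
    >= 0))
  expect_error(kl_standard_normal(list(mu_z = matrix(0, 1, 1),
                                       sigma_z = matrix(0, 1, 1))),
               "positive")
})

test_that("supervised L1 loss behaves as a bounded symmetric distance", {
  p <- matrix(c(0.5, 0.5), 1, 2)
  q <- matrix(c(1, 0), 1, 2)
  expect_equal(supervised_loss(p, p), 0)
  expect_equal(supervised_loss(p, q), 1)
  expect_equal(supervised_loss(q, matrix(c(0, 1), 1, 2)), 2)
  expect_equal(supervised_loss(p, q), supervised_loss(q, p))
  expect_error(supervised_loss(matrix(c(0.7, 0.7), 1, 2), q), "sum to 1")
})

test_that("the ELBO reconstruction matches the hand-computed toy", {
  m <- toy_one_gene_model()
  X <- matrix(0, 1, 1, dimnames = list("s1", "g1"))
  el <- elbo_loss(m, X, seed = 3)
  # y forced to 1 => mu = 1; -log NB(0; 1, 1) = log 2
  expect_equal(el$recon, log(2), tolerance = 1e-9)
  expect_equal(el$total, el$recon + el$kl)
})

test_that("loss is finite on an all-zero batch", {
  st <- small_study()
  m <- variational_model(st$ref$profile, latent_dim = 3, hidden = c(8, 8),
                         seed = 2, use_size_factor = FALSE)
  X0 <- st$tis$counts[1:4, ] * 0
  el <- elbo_loss(m, X0, seed = 1)
  expect_true(is.finite(el$total))
})

test_that("analytic gradients match finite differences", {
  st <- small_study()
  X <- st$tis$counts[1:4, 1:25]
  u <- st$ref$profile$u[, 1:25]
  prof <- reference_profile(u, st$ref$profile$beta[1:25])
  Yt <- st$tis$props[3:4, ]
  sup <- c(FALSE, FALSE, TRUE, TRUE)
  lib <- rowSums(X) / max(1, median(rowSums(X)))
  for (lik in c("nb", "poisson", "zinb")) {
    m <- variational_model(prof, latent_dim = 3, hidden = c(6, 5),
                           likelihood = lik, seed = 11)
    set.seed(2)
    eps <- matrix(rnorm(4 * 3), 4, 3)
    lg <- spotsparse:::loss_grad(m$par, m, X, lib, eps, sup, Yt)
    f <- function(par) {
      spotsparse:::loss_grad(par, m, X, lib, eps, sup, Yt)$total
    }
    set.seed(5)
    worst <- 0
    for (nm in names(m$par)) {
      for (r in 1:2) {
        i <- sample(length(m$par[[nm]]), 1)
        h <- 1e-5 * max(1, abs(m$par[[nm]][i]))
        p1 <- m$par; p1[[nm]][i] <- p1[[nm]][i] + h
        p2 <- m$par; p2[[nm]][i] <- p2[[nm]][i] - h
        num <- (f(p1) - f(p2)) / (2 * h)
        ana <- lg$grads[[nm]][i]
        if (abs(num) > 1e-10 || abs(ana) > 1e-10) {
          worst <- max(worst, abs(num - ana) / max(abs(num), abs(ana)))
        }
      }
    }
    expect_lt(worst, 1e-4)
  }
})

test_that("without pseudo-spots and supervision the objective is recon + KL", {
  st <- small_study()
  m <- variational_model(st$ref$profile, latent_dim = 3, hidden = c(8, 8),
                         seed = 2)
  m$ref_depth <- median(rowSums(st$tis$counts))
  X <- st$tis$counts[1:16, ]
  lib <- rowSums(X) / m$ref_depth
  set.seed(1)
  eps <- matrix(rnorm(16 * 3), 16, 3)
  lg <- spotsparse:::loss_grad(m$par, m, X, lib, eps,
                               supervised_weight = 0)
  expect_equal(lg$supervised, 0)
  expect_equal(lg$total, lg$recon + lg$kl)
})

test_that("zero epochs return the model unchanged", {
  st <- small_study()
  m <- variational_model(st$ref$profile, seed = 4)
  fit <- train(m, st$tis$counts, config = training_config(epochs = 0))
  expect_identical(fit$model, m)
  expect_equal(nrow(fit$history), 0)
})

test_that("training reduces the loss and is seed-deterministic", {
  st <- small_study()
  prof <- estimate_signatures(st$ref$counts, st$ref$labels)
  ps <- generate_pseudo_spots(st$ref$counts, st$ref$labels, 200,
                              cells_per_spot = c(1, 2),
                              target_umi = median(rowSums(st$tis$counts)),
                              seed = 8)
  m <- variational_model(prof, latent_dim = 5, hidden = c(32, 32), seed = 1)
  cfg <- training_config(epochs = 12, batch_size = 64, seed = 1,
                         patience = 20)
  fit <- train(m, st$tis$counts, ps, cfg)
  expect_lt(fit$history$total[nrow(fit$history)], fit$history$total[1])
  expect_true(all(fit$history$kl >= 0))
  expect_equal(fit$history$total,
               fit$history$recon + fit$history$kl + fit$history$supervised)
  fit2 <- train(m, st$tis$counts, ps, cfg)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$model$par, fit2$model$par)

  # inference: simplex rows, deterministic, sparse
  Y <- deconvolve(fit, st$tis$counts)
  expect_equal(dim(Y), c(200, 3))
  expect_rows_on_simplex(Y)
  expect_identical(deconvolve(fit, st$tis$counts), Y)
  expect_identical(deconvolve(fit, st$tis$counts, batch_size = 37), Y)
  expect_lte(mean(rowSums(Y > 0)), st$cfg$k_max + 2)
})

test_that("empty spatial data and NaN-free guards are enforced", {
  st <- small_study()
  m <- variational_model(st$ref$profile, seed = 4)
  expect_error(train(m, st$tis$counts[0, , drop = FALSE]), "empty")
})

test_that("the supervised-only warm-up runs and helps the pseudo loss", {
  st <- small_study()
  ps <- generate_pseudo_spots(st$ref$counts, st$ref$labels, 150,
                              cells_per_spot = c(1, 2), seed = 3)
  m <- variational_model(st$ref$profile, latent_dim = 4,
                         hidden = c(16, 16), seed = 2)
  cfg <- training_config(epochs = 3, pretrain_epochs = 3, batch_size = 64,
                         seed = 1, patience = 10)
  fit <- train(m, st$tis$counts, ps, cfg)
  expect_equal(nrow(fit$history), 3)
  expect_true(all(is.finite(fit$history$total)))
})
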