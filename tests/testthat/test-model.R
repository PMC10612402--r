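make_tiny_model <- function(likelihood = "nb", seed = 11, T_ = 3, G_ = 20,
                            D = 3) {
  set.seed(seed + 100)
  u <- matrix(rlnorm(T_ * G_), T_, G_,
              dimnames = list(paste0("t", 1:T_), paste0("g", 1:G_)))
  prof <- reference_profile(u, runif(G_, 1, 10))
  variational_model(prof, latent_dim = D, hidden = c(8, 6),
                    likelihood = likelihood, seed = seed)
}

test_that("encode is deterministic, shaped (N, D), and non-constant", {
  m <- make_tiny_model()
  set.seed(1)
  X <- matrix(rpois(5 * 20, 3), 5, 20)
  X[2, ] <- X[1, ]
  enc <- encode(m, X)
  expect_equal(dim(enc$mu_z), c(5, 3))
  expect_equal(dim(enc$sigma_z), c(5, 3))
  expect_true(all(enc$sigma_z > 0))
  expect_equal(enc$mu_z[1, ], enc$mu_z[2, ])
  expect_identical(encode(m, X), enc)
  # perturbing one input changes the output
  X2 <- X
  X2[1, 5] <- X2[1, 5] + 25
  enc2 <- encode(m, X2)
  expect_gt(max(abs(enc2$mu_z[1, ] - enc$mu_z[1, ])), 0)
  expect_error(encode(m, X[, 1:10]), "mismatch")
})

test_that("reparameterization satisfies Z = mu + sigma * eps exactly", {
  enc <- list(mu_z = matrix(c(1, -2), 2, 3), sigma_z = matrix(0.5, 2, 3))
  lat <- reparameterize(enc, seed = 4)
  expect_equal(lat$z, enc$mu_z + enc$sigma_z * lat$z_std)
  expect_identical(reparameterize(enc, seed = 4), lat)
  # sigma at the floor leaves z ~ mu
  enc0 <- list(mu_z = matrix(3, 2, 2), sigma_z = matrix(1e-4, 2, 2))
  expect_equal(reparameterize(enc0, seed = 1)$z, enc0$mu_z,
               tolerance = 1e-2)
})

test_that("latent draws are standard normal (Monte-Carlo moments)", {
  enc <- list(mu_z = matrix(0, 1e4, 1), sigma_z = matrix(1, 1e4, 1))
  z <- reparameterize(enc, seed = 7)$z
  expect_lt(abs(mean(z)), 4 / sqrt(1e4))
  expect_lt(abs(var(as.vector(z)) - 1), 0.05)
})

test_that("decode puts rows on the simplex with genuine sparsity", {
  m <- make_tiny_model(T_ = 20, G_ = 30, D = 10)
  set.seed(3)
  Z <- matrix(rnorm(100 * 10), 100, 10)
  Y <- decode(m, Z)
  expect_equal(dim(Y), c(100, 20))
  expect_rows_on_simplex(Y)
  expect_true(any(Y == 0))          # exact zeros off the support
  expect_lt(mean(rowSums(Y > 0)), 20)  # mean support strictly below T
  expect_identical(decode(m, Z), Y)
  expect_error(decode(m, Z[, 1:3]), "mismatch")
})

test_that("expected expression matches a hand-looped evaluation", {
  set.seed(9)
  Tt <- 3; G <- 5; N <- 4
  u <- matrix(rlnorm(Tt * G), Tt, G,
              dimnames = list(paste0("t", 1:Tt), paste0("g", 1:G)))
  prof <- reference_profile(u, rep(2, G))
  Y <- t(apply(matrix(runif(N * Tt), N, Tt), 1, function(r) r / sum(r)))
  s <- runif(G, 0.5, 2)
  gam <- runif(G, 0, 0.1)
  lib <- runif(N, 0.5, 2)
  mu <- expected_expression(Y, prof, s = s, gamma = gam, library = lib)
  hand <- matrix(0, N, G)
  for (i in 1:N) for (g in 1:G) {
    hand[i, g] <- lib[i] * (s[g] * sum(Y[i, ] * u[, g]) + gam[g])
  }
  expect_lt(max(abs(mu - hand)), 1e-12)

  # one-hot mixture returns the type's signature row
  Y1 <- matrix(c(0, 1, 0), 1, 3)
  expect_equal(as.vector(expected_expression(Y1, prof)), unname(u[2, ]))
  # pure additive noise
  prof0 <- reference_profile(u * 0, rep(2, G))
  expect_true(all(expected_expression(Y1, prof0, gamma = 0.3) == 0.3))
  expect_error(expected_expression(Y1, prof, s = -1), "positive")
  expect_error(expected_expression(Y1, prof, gamma = -0.1), "non-negative")
})

test_that("the feed-forward ablation maps counts to the simplex", {
  st <- small_study()
  dnn <- dnn_model(st$ref$profile, hidden = c(16, 16), seed = 3)
  X <- st$tis$counts[1:30, ]
  Y <- dnn_forward(dnn, X)
  expect_rows_on_simplex(Y)
  expect_identical(dnn_forward(dnn, X), Y)
  expect_error(dnn_forward(dnn, X[, 1:5]), "mismatch")
  # one supervised epoch yields a finite loss
  ps <- generate_pseudo_spots(st$ref$counts, st$ref$labels, 60, seed = 4)
  fit <- train_dnn(dnn, ps, training_config(epochs = 1, batch_size = 20,
                                            seed = 2))
  expect_true(is.finite(fit$history$supervised[1]))
})

test_that("checkpoints reload to an identical model", {
  m <- make_tiny_model()
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  set.seed(2)
  X <- matrix(rpois(4 * 20, 3), 4, 20)
  expect_identical(deconvolve(m2, X), deconvolve(m, X))
})
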