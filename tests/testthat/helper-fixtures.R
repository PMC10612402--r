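# Shared fixtures and independent oracles, built in code at test time.

# small synthetic study reused by several files (memoised per test run)
.fixture_env <- new.env(parent = emptyenv())

small_study <- function() {
  if (is.null(.fixture_env$study)) {
    cfg <- sim_config(n_types = 3, n_genes = 60, n_cells_per_type = 60,
                      n_spots = 200, markers_per_type = 5, k_max = 2,
                      mean_umi = 100, seed = 7)
    ref <- simulate_reference(cfg)
    tis <- simulate_tissue(cfg, ref$profile)
    .fixture_env$study <- list(cfg = cfg, ref = ref, tis = tis)
  }
  .fixture_env$study
}

# independent simplex-projection oracle: solve the water-filling equation
# sum_j max(v_j - tau, 0) = 1 for tau by bisection (no sorting involved)
proj_simplex_oracle <- function(v) {
  f <- function(tau) sum(pmax(v - tau, 0)) - 1
  lo <- min(v) - 1 / length(v) - 1
  hi <- max(v)
  tau <- uniroot(f, c(lo, hi), tol = 1e-14)$root
  pmax(v - tau, 0)
}

# KL(N(mu, sigma^2) || N(0,1)) by numerical quadrature, per dimension
kl_quadrature <- function(mu, sigma) {
  sum(mapply(function(m, s) {
    integrand <- function(x) {
      q <- dnorm(x, m, s)
      lr <- dnorm(x, m, s, log = TRUE) - dnorm(x, log = TRUE)
      ifelse(q > 0, q * lr, 0)
    }
    integrate(integrand, m - 12 * s, m + 12 * s,
              rel.tol = 1e-10)$value
  }, mu, sigma))
}

# brute-force Spearman: Pearson correlation of average ranks
spearman_oracle <- function(x, y) {
  cor(rank(x), rank(y))
}

expect_rows_on_simplex <- function(Y, tol = 1e-6) {
  expect_true(all(Y >= -tol & Y <= 1 + tol))
  expect_true(max(abs(rowSums(Y) - 1)) < tol)
}
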