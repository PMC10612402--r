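test_that("marker correlation recovers exact monotone relationships", {
  n <- 40
  set.seed(2)
  expr <- matrix(rpois(n * 2, 10), n, 2,
                 dimnames = list(paste0("s", 1:n), c("gA", "gB")))
  props <- cbind(A = expr[, "gA"] / max(expr[, "gA"]),
                 B = 1 - expr[, "gA"] / max(expr[, "gA"]))
  # avoid accidental 0/1 overshoot: rescale into the simplex
  props <- props / rowSums(props)
  rownames(props) <- rownames(expr)
  tab <- marker_correlation(props, expr, list(A = "gA"))
  expect_equal(tab$rho, 1)
  tabr <- marker_correlation(cbind(A = props[, 2], B = props[, 1]),
                             expr, list(A = "gA"))
  expect_equal(tabr$rho, -1)
})

test_that("Spearman matches a brute-force rank computation with ties", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(5, 4, 3, 1, 2)  # reverse with last two swapped
  props <- cbind(A = x / sum(x) * 0 + x / 15, B = 1 - x / 15)
  spatial <- matrix(y, 5, 1, dimnames = list(NULL, "g"))
  tab <- marker_correlation(props, spatial, list(A = "g"))
  expect_equal(tab$rho, spearman_oracle(x, y))
  # with ties (average ranks)
  y2 <- c(2, 2, 1, 5, 4)
  tab2 <- marker_correlation(props, matrix(y2, 5, 1,
                                           dimnames = list(NULL, "g")),
                             list(A = "g"))
  expect_equal(tab2$rho, spearman_oracle(x, y2))
})

test_that("marker correlation is invariant to monotone transforms", {
  set.seed(6)
  x <- runif(30)
  props <- cbind(A = x, B = 1 - x)
  y <- rpois(30, 5)
  spatial <- matrix(y, 30, 1, dimnames = list(NULL, "g"))
  r1 <- marker_correlation(props, spatial, list(A = "g"))$rho
  spatial2 <- matrix(exp(y / 2), 30, 1, dimnames = list(NULL, "g"))
  # transformed expression is no longer integer counts, but correlation
  # only sees ranks; call on the raw matrix directly
  r2 <- marker_correlation(props, spatial2, list(A = "g"))$rho
  expect_equal(r1, r2)
})

test_that("zero-variance vectors give NA, and missing markers are skipped", {
  props <- cbind(A = rep(0.5, 10), B = rep(0.5, 10))
  spatial <- matrix(rpois(10, 3), 10, 1, dimnames = list(NULL, "g"))
  tab <- marker_correlation(props, spatial, list(A = "g"))
  expect_true(is.na(tab$rho))
  expect_message(
    tab2 <- marker_correlation(props, spatial, list(A = c("g", "absent"))),
    "skipped")
  expect_equal(nrow(tab2), 1)
})

test_that("Moran's I equals -1 on the alternating line", {
  vals <- c(1, -1, 1, -1)
  A <- matrix(0, 4, 4)
  A[cbind(1:3, 2:4)] <- 1
  A[cbind(2:4, 1:3)] <- 1
  W <- A / rowSums(A)
  expect_equal(morans_i(vals, W), -1, tolerance = 1e-12)
})

test_that("Moran's I is positive on a gradient and null under shuffling", {
  grid <- expand.grid(x = 1:10, y = 1:10)
  co <- spot_coords(paste0("s", 1:100), as.matrix(grid))
  W <- knn_graph(co, k = 4)
  smooth <- grid$x + grid$y
  expect_gt(morans_i(smooth, W), 0)
  set.seed(31)
  null_i <- replicate(200, morans_i(sample(smooth), W))
  expect_lt(abs(morans_i(sample(smooth), W) - (-1 / 99)),
            3 * sd(null_i) + 1e-12)
  expect_lt(abs(mean(null_i) - (-1 / 99)), 3 * sd(null_i) / sqrt(200))
  expect_true(all(abs(null_i) <= 1.5))
  expect_warning(res <- morans_i(rep(1, 100), W), "constant")
  expect_true(is.na(res))
})

test_that("Moran's I agrees with the ape implementation", {
  skip_if_not_installed("ape")
  set.seed(9)
  co <- spot_coords(paste0("s", 1:50), matrix(runif(100), 50, 2))
  W <- knn_graph(co, k = 5)
  x <- rnorm(50)
  ours <- morans_i(x, W)
  theirs <- ape::Moran.I(x, as.matrix(W), scaled = FALSE)$observed
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("JS distance is a bounded metric with closed-form extremes", {
  expect_equal(js_distance(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(js_distance(c(1, 0), c(0, 1)), 1)
  set.seed(4)
  for (i in 1:100) {
    r <- function() {
      v <- runif(4)
      v / sum(v)
    }
    p <- r(); q <- r(); s <- r()
    expect_equal(js_distance(p, q), js_distance(q, p))
    expect_lte(js_distance(p, q),
               js_distance(p, s) + js_distance(s, q) + 1e-12)
    expect_true(js_distance(p, q) >= 0 && js_distance(p, q) <= 1)
  }
  expect_error(js_distance(c(-0.1, 1.1), c(0.5, 0.5)), "non-negative")
  expect_error(js_distance(c(0.4, 0.4), c(0.5, 0.5)), "sum to 1")
  expect_warning(js_distance(c(0.5, 0.5 - 1e-8), c(0.5, 0.5)),
                 "renormalizing")
})

test_that("evaluate_run reports one row per type and sane summaries", {
  st <- small_study()
  markers <- st$ref$markers
  ev <- evaluate_run(st$tis$props, st$tis$counts, st$tis$coords, markers)
  expect_s3_class(ev$per_type, "tbl_df")
  expect_equal(nrow(ev$per_type), length(markers))
  # true proportions of a banded tissue are spatially autocorrelated and
  # match their own markers (self-consistency upper bound)
  expect_true(all(ev$per_type$morans_i > 0))
  direct <- marker_correlation(st$tis$props, st$tis$counts, markers)
  expect_equal(median(ev$per_type$median_rho),
               median(tapply(direct$rho, direct$cell_type, median)))
  expect_true(all(ev$per_spot$js >= 0 & ev$per_spot$js <= 1, na.rm = TRUE))

  # shuffled proportions: spatial signal collapses to the permutation null
  set.seed(13)
  shuf <- st$tis$props[sample(nrow(st$tis$props)), ]
  rownames(shuf) <- rownames(st$tis$props)
  ev2 <- evaluate_run(shuf, st$tis$counts, st$tis$coords, markers)
  # null expectation is -1/(n-1) with sd of order 1/sqrt(n)
  n <- nrow(shuf)
  expect_lt(max(abs(ev2$per_type$morans_i - (-1 / (n - 1)))),
            3 / sqrt(n))
  expect_lt(median(ev2$per_type$morans_i),
            median(ev$per_type$morans_i) / 2)
})
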