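test_that("Bland-Altman matches hand-computed cases", {
  x <- c(10, 20, 30, 40)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))
  ba1 <- bland_altman(x + 1, x)       # d = {1,1,1,1}
  expect_equal(ba1$bias, 1)
  expect_equal(ba1$sd_diff, 0)
  expect_equal(c(ba1$loa_low, ba1$loa_high), c(1, 1))
  ba2 <- bland_altman(c(10, 22), c(10, 20))   # d = {0, 2}
  expect_equal(ba2$bias, 1)
  expect_equal(ba2$sd_diff, sqrt(2))
  expect_equal(ba2$loa_low, 1 - 1.96 * sqrt(2))
  expect_equal(ba2$loa_high, 1 + 1.96 * sqrt(2))
  # antisymmetry
  set.seed(4); a <- rnorm(20); b <- rnorm(20)
  expect_equal(bland_altman(a, b)$bias, -bland_altman(b, a)$bias)
  expect_equal(bland_altman(a, b)$loa_low, -bland_altman(b, a)$loa_high)
  expect_error(bland_altman(1:3, 1:4), "equal length")
  expect_error(bland_altman(1, 2), "at least 2")
})

test_that("proportional bias regression has its closed-form anchors", {
  x <- c(10, 20, 30, 40, 50)
  pb0 <- proportional_bias(x + 3, x)   # constant difference
  expect_equal(pb0$slope, 0)
  expect_equal(pb0$t, 0)
  m <- c(10, 20, 30, 40)
  d <- 0.5 * m
  pb1 <- proportional_bias(m + d / 2, m - d / 2)  # d = 0.5 * mean exactly
  expect_equal(pb1$slope, 0.5)
  expect_equal(pb1$p, 0, tolerance = 1e-10)
  expect_error(proportional_bias(c(5, 5, 5), c(5, 5, 5)), "zero variance")
})

test_that("proportional bias test is calibrated and powered (Monte Carlo)", {
  reject <- function(slope, reps) {
    mean(vapply(seq_len(reps), function(i) {
      m <- runif(40, 10, 30)
      d <- slope * m + rnorm(40, 0, 1)
      proportional_bias(m + d / 2, m - d / 2)$p < 0.05
    }, logical(1)))
  }
  set.seed(99)
  expect_lt(abs(reject(0, 1000) - 0.05), 0.02)   # type-I error ~ alpha
  expect_gt(reject(0.3, 200), 0.9)               # clear power under bias
})

test_that("Spearman matches the reference implementation", {
  # hand-ranked case: ranks (1,2,3) vs (2,1,3) -> rho = 0.5
  expect_equal(spearman_rho(c(1, 2, 3), c(2, 1, 3))$rho, 0.5)
  expect_equal(spearman_rho(1:10, (1:10)^3)$rho, 1)
  set.seed(31)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    x <- rnorm(n); y <- 0.5 * x + rnorm(n)
    if (i %% 3 == 0) { x <- round(x, 1); y <- round(y, 1) }  # force ties
    if (sd(x) == 0 || sd(y) == 0) next
    got <- spearman_rho(x, y)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman",
                                     exact = FALSE))
    expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-8)
    expect_equal(got$p, ref$p.value, tolerance = 1e-8)
  }
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
})

test_that("Wilcoxon signed-rank matches the reference implementation", {
  # all-zero differences carry no signal
  z <- wilcoxon_signed_rank(1:5, 1:5)
  expect_equal(z$n, 0L)
  expect_equal(z$p, 1)
  set.seed(17)
  for (i in 1:100) {
    n <- sample(c(8:20, 30:50), 1)
    x <- rnorm(n); y <- rnorm(n, 0.3)
    got <- wilcoxon_signed_rank(x, y)
    exact <- got$method == "exact"
    ref <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = exact,
                                        correct = TRUE))
    expect_equal(unname(got$statistic), unname(ref$statistic),
                 tolerance = 1e-8)
    expect_equal(got$p, ref$p.value, tolerance = 1e-8)
  }
  # ties force the normal approximation even at small n
  xt <- c(1, 2, 3, 4, 5, 6, 7, 8)
  yt <- c(2, 1, 5, 2, 7, 3, 10, 4)
  gt <- wilcoxon_signed_rank(xt, yt)
  rt <- suppressWarnings(wilcox.test(xt, yt, paired = TRUE, exact = FALSE,
                                     correct = TRUE))
  expect_equal(gt$p, rt$p.value, tolerance = 1e-8)
})

test_that("pointwise bias maps localise simulated offsets", {
  g <- build_grid("SPARK66")
  set.seed(8)
  a <- matrix(rnorm(20 * 66, 28, 2), nrow = 20)
  expect_true(all(pointwise_bias_map(a, a)$bias == 0))
  pm <- pointwise_bias_map(a + 2, a, grid = g)
  expect_equal(pm$bias, rep(2, 66))
  expect_equal(attr(pm, "convention"), "difference = a - b")
  # nasal-only offset stays nasal
  b <- a
  nasal <- g$points$x < 0
  b[, nasal] <- b[, nasal] + 3
  pm2 <- pointwise_bias_map(b, a, grid = g)
  expect_equal(pm2$bias[nasal], rep(3, sum(nasal)))
  expect_equal(pm2$bias[!nasal], rep(0, sum(!nasal)))
  expect_error(pointwise_bias_map(a, a[1:10, ]), "identical dimensions")
})
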