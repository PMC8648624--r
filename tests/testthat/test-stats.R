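test_that("Bland-Altman limits of agreement follow mean +/- 1.96 SD", {
  # vector constructed to have mean 123.1 and SD 76.1 exactly
  d <- c(123.1 - 76.1, 123.1, 123.1 + 76.1)
  expect_equal(mean(d), 123.1, tolerance = 1e-12)
  expect_equal(sd(d), 76.1, tolerance = 1e-12)
  ba <- bland_altman(d)
  expect_equal(round(ba$loa_low, 1), -26.1)
  expect_equal(round(ba$loa_high, 1), 272.3)

  cb <- bland_altman(rep(4.2, 5))
  expect_identical(cb$sd, 0)
  expect_identical(cb$loa_low, cb$loa_high)
  expect_identical(cb$loa_low, 4.2)

  set.seed(14)
  for (i in 1:5) {
    v <- rnorm(20, 50, 30)
    ba <- bland_altman(v)
    # brute-force mean/SD oracle
    m <- sum(v) / 20
    s <- sqrt(sum((v - m)^2) / 19)
    expect_equal(ba$mean, m, tolerance = 1e-12)
    expect_equal(ba$sd, s, tolerance = 1e-12)
    expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96 * s, tolerance = 1e-12)
  }
  expect_error(bland_altman(3), "two")
})

test_that("single-measure absolute-agreement ICC matches its oracles", {
  # identical columns: perfect agreement
  v <- c(3, 7, 5, 9, 4)
  expect_equal(icc_single(cbind(v, v))$icc, 1, tolerance = 1e-12)

  # frozen external reference (two-way random, absolute agreement, single
  # measure) for a fixed 8 x 2 table
  vals <- matrix(c(9.1, 9.4, 6.2, 7.0, 7.7, 7.5, 8.4, 9.0,
                   5.5, 5.1, 7.1, 7.8, 8.9, 8.6, 6.6, 6.9),
                 ncol = 2, byrow = TRUE)
  r <- icc_single(vals)
  expect_equal(r$icc, 0.9326857030713374, tolerance = 1e-6)
  expect_equal(round(r$ci_low, 2), 0.72)
  expect_equal(round(r$ci_high, 2), 0.99)

  # ANOVA mean-squares oracle on a 6 x 2 hand table
  h <- matrix(c(1.2, 1.9, 2.4, 2.2, 3.1, 3.7, 4.0, 4.6, 5.5, 5.1, 6.3, 6.9),
              ncol = 2, byrow = TRUE)
  fit <- stats::aov(y ~ subj + rater,
                    data = data.frame(y = as.vector(h),
                                      subj = factor(rep(1:6, 2)),
                                      rater = factor(rep(1:2, each = 6))))
  ms <- summary(fit)[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- 6; k <- 2
  icc_oracle <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  expect_equal(icc_single(h)$icc, icc_oracle, tolerance = 1e-10)

  # independent noise: near-zero ICC at n = 200
  set.seed(42)
  noise <- cbind(rnorm(200), rnorm(200))
  expect_lt(abs(icc_single(noise)$icc), 0.2)

  # invariance to adding a constant to both columns
  expect_equal(icc_single(vals + 100)$icc, r$icc, tolerance = 1e-9)

  expect_error(icc_single(matrix(2, 5, 2)), "variance")
  expect_error(icc_single(vals[1:2, ]), "3 subjects")
})

test_that("Cronbach's alpha matches the covariance-matrix identity", {
  v <- c(3, 7, 5, 9, 4, 6)
  expect_equal(cronbach_alpha(cbind(v, v)), 1, tolerance = 1e-12)

  set.seed(10)
  for (k in c(2, 4)) {
    m <- matrix(rnorm(30 * k), 30, k) + rnorm(30)
    a <- cronbach_alpha(m)
    cc <- stats::cov(m)
    oracle <- k / (k - 1) * (1 - sum(diag(cc)) / sum(cc))
    expect_equal(a, oracle, tolerance = 1e-12)
  }

  # frozen external reference for the 8 x 2 agreement table
  vals <- matrix(c(9.1, 9.4, 6.2, 7.0, 7.7, 7.5, 8.4, 9.0,
                   5.5, 5.1, 7.1, 7.8, 8.9, 8.6, 6.6, 6.9),
                 ncol = 2, byrow = TRUE)
  expect_equal(cronbach_alpha(vals), 0.968317033414833, tolerance = 1e-6)

  # uncorrelated items: alpha near zero
  set.seed(77)
  expect_lt(abs(cronbach_alpha(cbind(rnorm(500), rnorm(500)))), 0.15)

  # invariance to common rescaling
  expect_equal(cronbach_alpha(vals * 3.7), cronbach_alpha(vals),
               tolerance = 1e-12)
  expect_error(cronbach_alpha(matrix(1, 4, 2)), "variance")
})

test_that("paired t test matches the closed form", {
  x <- c(5.1, 4.8, 6.0, 5.5, 4.9, 6.2, 5.8)
  expect_equal(paired_t(x, x), list(t = 0, df = 6, p = 1))

  y <- c(4.6, 4.9, 5.2, 5.3, 4.1, 5.9, 5.0)
  r <- paired_t(x, y)
  d <- x - y; n <- length(d)
  t_oracle <- mean(d) / (sd(d) / sqrt(n))
  p_oracle <- 2 * stats::pt(-abs(t_oracle), n - 1)
  expect_equal(r$t, t_oracle, tolerance = 1e-6)
  expect_identical(r$df, n - 1)
  expect_equal(r$p, p_oracle, tolerance = 1e-6)

  expect_error(paired_t(1, 2), "two pairs")
  expect_error(paired_t(c(1, 2, 3), c(0, 1, 2)), "constant")
})

test_that("Pearson correlation matches the covariance formula", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_r(x, -x)$r, -1, tolerance = 1e-12)

  set.seed(23)
  a <- rnorm(40); b <- 0.4 * a + rnorm(40)
  r <- pearson_r(a, b)
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(r$r, oracle, tolerance = 1e-6)
  t_o <- oracle * sqrt(38 / (1 - oracle^2))
  expect_equal(r$p, 2 * stats::pt(-abs(t_o), 38), tolerance = 1e-6)

  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(pearson_r(1:2, 1:2), "three")
})

test_that("reclassification counts subjects crossing the 25% threshold", {
  d <- c(30, 40, 10, 26, 24)
  same <- reclassification_table(rep(3, 5), rep(3, 5), d, d)
  expect_identical(same$insig_to_sig, 0L)
  expect_identical(same$sig_to_insig, 0L)
  expect_identical(same$unchanged, 5L)

  # 70 of 72 significant reports as 97%
  d72 <- c(rep(60, 70), 10, 10)
  r <- reclassification_table(rep(3, 72), rep(3, 72), d72, d72)
  expect_identical(r$pct_sig_a, 97L)

  # constructed vectors straddling the threshold vs brute force
  da <- c(20, 30, 24, 40, 26, 10)
  db <- c(30, 20, 26, 45, 24, 12)
  r2 <- reclassification_table(seq_len(6), seq_len(6), da, db)
  expect_identical(r2$insig_to_sig, sum(da <= 25 & db > 25))
  expect_identical(r2$sig_to_insig, sum(da > 25 & db <= 25))
  expect_identical(r2$unchanged, sum((da > 25) == (db > 25)))

  expect_error(reclassification_table(1:3, 1:3, 1:3, 1:2), "lengths")
})
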