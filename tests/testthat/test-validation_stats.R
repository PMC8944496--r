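test_that("perfect agreement gives the ideal index values", {
  v <- validate_model(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(v$d, 1)
  expect_equal(v$ef, 1)
  expect_equal(v$rmse, 0)
  expect_equal(v$mbe, 0)
  expect_equal(v$r2, 1)
})

test_that("predicting the observed mean gives zero model efficiency", {
  obs <- c(2, 4, 6, 8)
  v <- validate_model(obs, rep(mean(obs), 4))
  expect_equal(v$ef, 0)
})

test_that("a constant +1 offset shows as overestimation", {
  v <- validate_model(c(1, 2, 3), c(2, 3, 4))
  expect_equal(v$mbe, 1)                    # positive = overestimation
  expect_equal(v$rmse, 1)
  expect_equal(v$r2, 1)
})

test_that("degenerate inputs are rejected with informative errors", {
  expect_error(validate_model(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(validate_model(1:3, 1:4), "equal length")
  expect_error(validate_model(1, 1), "at least 2")
})

test_that("the bias-variance identity and index bounds hold on random pairs", {
  set.seed(5)
  for (i in 1:30) {
    n <- sample(5:60, 1)
    obs <- rnorm(n, 10, 3)
    sim <- obs + rnorm(n, runif(1, -2, 2), runif(1, 0.1, 3))
    v <- validate_model(obs, sim)
    err <- sim - obs
    # RMSE^2 = MBE^2 + population variance of the errors
    expect_equal(v$rmse^2, v$mbe^2 + mean((err - mean(err))^2),
                 tolerance = 1e-10)
    expect_gte(v$rmse, abs(v$mbe))
    expect_true(v$d >= 0 && v$d <= 1)
    expect_lte(v$ef, 1)
    expect_lt(v$d, 1)                        # not identical -> strictly < 1
    # r2 agrees with the squared correlation from stats
    expect_equal(v$r2, cor(obs, sim)^2)
  }
})

test_that("orthogonal designs have unit VIF, duplicates are flagged infinite", {
  d <- data.frame(a = rep(c(-1, 1), each = 4), b = rep(c(-1, 1), 4))
  expect_equal(unname(vif(d)), c(1, 1))
  d2 <- data.frame(a = rnorm(20))
  d2$b <- d2$a
  expect_true(is.infinite(vif(d2)[["b"]]))
  expect_equal(unname(vif(d2["a"])), 1)
})

test_that("VIF agrees with the car reference on a correlated design", {
  skip_if_not_installed("car")
  set.seed(12)
  d <- data.frame(x1 = rnorm(80))
  d$x2 <- 0.8 * d$x1 + rnorm(80, 0, 0.5)
  d$x3 <- rnorm(80)
  d$y <- d$x1 + d$x2 + d$x3 + rnorm(80)
  ref <- car::vif(lm(y ~ x1 + x2 + x3, data = d))
  expect_equal(vif(d[c("x1", "x2", "x3")]), ref[c("x1", "x2", "x3")],
               tolerance = 1e-8)
})

test_that("Durbin-Watson is near 2 for white noise and agrees with lmtest", {
  set.seed(6)
  e <- rnorm(4000)
  expect_equal(durbin_watson(e), 2, tolerance = 0.1)
  skip_if_not_installed("lmtest")
  d <- data.frame(x = rnorm(100))
  d$y <- 2 * d$x + rnorm(100)
  fit <- lm(y ~ x, data = d)
  ref <- unname(lmtest::dwtest(fit)$statistic)
  expect_equal(durbin_watson(residuals(fit)), ref, tolerance = 1e-8)
  expect_error(durbin_watson(1), ">= 2")
})

test_that("validation reports serialize to CSV", {
  reports <- list(feces = validate_model(c(1, 2, 3), c(1.1, 2.2, 2.9)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_validation_reports(reports, path)
  tab <- read.csv(path)
  expect_equal(tab$model, "feces")
  expect_named(tab, c("model", "n", "d", "r2", "rmse", "mbe", "ef"))
})
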