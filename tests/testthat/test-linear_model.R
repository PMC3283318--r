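test_that("exact linear data are recovered exactly", {
  d <- data.frame(y = c(1, 3, 5, 7, 9), x = 0:4)
  fit <- suppressWarnings(fit_ols(d, "x", response = "y"))
  expect_equal(fit$coefficients$estimate, c(1, 2), tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  d2 <- data.frame(y = 2 + 3 * seq(0, 1, length.out = 20), x = seq(0, 1, length.out = 20))
  fit2 <- suppressWarnings(fit_ols(d2, "x", response = "y"))
  expect_equal(fit2$coefficients$estimate, c(2, 3), tolerance = 1e-10)
})

test_that("under the null the slope and R2 vanish", {
  withr::with_seed(11, {
    d <- data.frame(y = rnorm(10000), x = rnorm(10000))
    fit <- fit_ols(d, "x", response = "y")
    expect_lt(abs(fit$coefficients$estimate[2]), 0.05)
    expect_lt(fit$r2, 0.01)
  })
})

test_that("residual invariants hold: zero sum and predictor orthogonality", {
  withr::with_seed(12, {
    d <- data.frame(y = rnorm(200), a = rnorm(200), b = runif(200))
    d$y <- d$y + 0.5 * d$a - 1 * d$b
    fit <- fit_ols(d, c("a", "b"), response = "y")
    expect_lt(abs(sum(fit$residuals)), 1e-8)
    expect_lt(abs(sum(fit$residuals * d$a)), 1e-8)
    expect_lt(abs(sum(fit$residuals * d$b)), 1e-8)
    expect_lte(fit$adj_r2, fit$r2)
  })
})

test_that("fit_ols agrees with the normal-equations oracle on random designs", {
  withr::with_seed(13, {
    for (i in 1:25) {
      n <- sample(10:50, 1)
      p <- sample(1:4, 1)
      X <- matrix(rnorm(n * p), n, p)
      y <- rnorm(n) + X %*% runif(p, -2, 2)
      colnames(X) <- paste0("X", seq_len(p))
      d <- data.frame(y = as.vector(y), X)
      fit <- fit_ols(d, paste0("X", seq_len(p)), response = "y")
      oracle <- normal_equations_ols(X, as.vector(y))
      expect_equal(fit$coefficients$estimate, oracle$beta, tolerance = 1e-8)
      expect_equal(fit$r2, oracle$r2, tolerance = 1e-8)
    }
  })
})

test_that("rank-deficient designs fail loudly, naming the collinear column", {
  d <- data.frame(y = rnorm(20), a = rnorm(20))
  d$b <- 2 * d$a
  expect_error(fit_ols(d, c("a", "b"), response = "y"),
               "rank deficient.*b")
  expect_error(fit_ols(d[1:2, ], "a", response = "y"), "more observations")
})

test_that("backward elimination removes the largest-p predictor stepwise", {
  withr::with_seed(14, {
    n <- 400
    d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), noise = rnorm(n))
    d$y <- 1 + 2 * d$x1 - 1.5 * d$x2 + rnorm(n)
    res <- backward_select(d, c("x1", "x2", "noise"), response = "y")
    expect_equal(sort(res$trace$final_predictors), c("x1", "x2"))
    expect_equal(res$trace$steps$removed, "noise")
    expect_gt(res$trace$steps$p_value, 0.05)
    # trace invariant: no surviving predictor with p above alpha
    pv <- res$fit$coefficients$p_value[res$fit$coefficients$term != "(Intercept)"]
    expect_true(all(pv <= 0.05))
  })
})

test_that("alpha = 1 removes nothing; alpha = 0 strips down to the intercept", {
  withr::with_seed(15, {
    n <- 100
    d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
    d$y <- 0.3 * d$x1 + rnorm(n)
    keep_all <- backward_select(d, c("x1", "x2"), response = "y", alpha = 1)
    expect_equal(keep_all$trace$final_predictors, c("x1", "x2"))
    expect_equal(nrow(keep_all$trace$steps), 0L)
    strip <- backward_select(d, c("x1", "x2"), response = "y", alpha = 0)
    expect_equal(length(strip$trace$final_predictors), 0L)
    expect_equal(strip$fit$r2, 0)
  })
})

test_that("a pure-noise candidate is eliminated at close to rate 1 - alpha", {
  withr::with_seed(16, {
    removed <- vapply(1:300, function(i) {
      n <- 150
      d <- data.frame(x = rnorm(n), junk = rnorm(n))
      d$y <- 1 + 1.5 * d$x + rnorm(n)
      res <- backward_select(d, c("x", "junk"), response = "y")
      !("junk" %in% res$trace$final_predictors)
    }, logical(1))
    expect_gt(mean(removed), 0.90)
  })
})

test_that("near-duplicated predictors either get pruned or raise a rank error", {
  withr::with_seed(17, {
    n <- 200
    d <- data.frame(x = rnorm(n))
    d$x_copy <- d$x + rnorm(n, sd = 1e-6)
    d$y <- 2 * d$x + rnorm(n)
    out <- tryCatch(backward_select(d, c("x", "x_copy"), response = "y"),
                    error = function(e) e)
    if (inherits(out, "error")) {
      expect_match(conditionMessage(out), "rank deficient")
    } else {
      expect_lte(length(out$trace$final_predictors), 1L)
    }
  })
})

test_that("VIF is 1 for orthogonal predictors and explodes for duplicates", {
  # balanced +/-1 factorial design: exactly orthogonal columns
  d <- expand.grid(a = c(-1, 1), b = c(-1, 1), c = c(-1, 1))
  v <- vif(d, c("a", "b", "c"))
  expect_equal(unname(v), rep(1, 3), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(length(attr(v, "flagged")), 0L)
  withr::with_seed(18, {
    n <- 200
    d2 <- data.frame(x1 = rnorm(n))
    d2$x2 <- d2$x1 + rnorm(n, sd = 0.01)
    d2$x3 <- rnorm(n)
    v2 <- vif(d2, c("x1", "x2", "x3"))
    expect_gt(v2[["x1"]], 10)
    expect_gt(v2[["x2"]], 10)
    expect_lt(v2[["x3"]], 2)
    expect_setequal(attr(v2, "flagged"), c("x1", "x2"))
    # exact duplicate: infinite, flagged
    d2$dup <- d2$x3
    v3 <- suppressWarnings(vif(d2, c("x3", "dup"))) # perfect fit expected
    expect_true(all(is.infinite(v3)))
  })
})

test_that("VIF matches car::vif and is invariant under affine rescaling", {
  skip_if_not_installed("car")
  withr::with_seed(19, {
    n <- 150
    d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
    d$x3 <- 0.6 * d$x1 + rnorm(n)
    d$y <- d$x1 + d$x2 + rnorm(n)
    mine <- vif(d, c("x1", "x2", "x3"))
    theirs <- car::vif(lm(y ~ x1 + x2 + x3, data = d))
    expect_equal(unname(mine), unname(theirs[names(mine)]), tolerance = 1e-10,
                 ignore_attr = TRUE)
    d_scaled <- d
    d_scaled$x1 <- 100 * d$x1 - 7
    rescaled <- vif(d_scaled, c("x1", "x2", "x3"))
    expect_equal(unname(rescaled), unname(mine), tolerance = 1e-9)
  })
})

test_that("iid predictors at large n have VIF near 1", {
  withr::with_seed(20, {
    d <- as.data.frame(matrix(rnorm(10000 * 4), ncol = 4))
    v <- vif(d, names(d))
    expect_true(all(abs(v - 1) < 0.02))
  })
})

test_that("RCVE recomputes from independently fitted full and reduced models", {
  withr::with_seed(21, {
    n <- 500
    d <- data.frame(big = rnorm(n), small = rnorm(n), tiny = rnorm(n))
    d$y <- 3 * d$big + 0.3 * d$small + 0.05 * d$tiny + rnorm(n)
    r <- rcve(d, c("big", "small", "tiny"), response = "y")
    # brute-force recomputation with plain lm
    r2 <- function(f) summary(lm(f, data = d))$r.squared
    full <- r2(y ~ big + small + tiny)
    for (j in c("big", "small", "tiny")) {
      red <- r2(reformulate(setdiff(c("big", "small", "tiny"), j),
                            response = "y"))
      expect_equal(r[[j]], (full - red) / full, tolerance = 1e-12)
    }
    expect_gt(r[["big"]], r[["small"]])
    expect_gt(r[["small"]], r[["tiny"]])
    expect_true(all(r >= 0))
  })
})

test_that("RCVE edge cases: single predictor gives 1, null predictor near 0", {
  withr::with_seed(22, {
    n <- 2000
    d <- data.frame(x = rnorm(n), junk = rnorm(n))
    d$y <- d$x + rnorm(n)
    expect_equal(unname(rcve(d, "x", response = "y")), 1, tolerance = 1e-12,
                 ignore_attr = TRUE)
    r <- rcve(d, c("x", "junk"), response = "y")
    expect_lt(r[["junk"]], 0.01)
  })
})

test_that("partial correlation: residual method equals the t-statistic formula", {
  withr::with_seed(23, {
    for (i in 1:10) {
      n <- 120
      d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
      d$y <- 0.8 * d$x1 - 0.5 * d$x2 + 0.1 * d$x3 + rnorm(n)
      fit <- fit_ols(d, c("x1", "x2", "x3"), response = "y")
      for (j in c("x1", "x2", "x3")) {
        pc <- partial_correlation(d, j, setdiff(c("x1", "x2", "x3"), j),
                                  response = "y")
        t_j <- fit$coefficients$t_value[fit$coefficients$term == j]
        expect_equal(pc, t_j / sqrt(t_j^2 + fit$df_residual),
                     tolerance = 1e-10)
        # sign agreement with the full-model coefficient
        expect_equal(sign(pc),
                     sign(fit$coefficients$estimate[
                       fit$coefficients$term == j]))
      }
    }
  })
})

test_that("partial correlation reduces to plain correlation with no controls", {
  withr::with_seed(24, {
    d <- data.frame(x = rnorm(80))
    d$y <- 0.5 * d$x + rnorm(80)
    expect_equal(partial_correlation(d, "x", character(0), response = "y"),
                 cor(d$x, d$y), tolerance = 1e-12)
    # independent target: near zero at large n
    d2 <- data.frame(x = rnorm(5000), z = rnorm(5000), y = rnorm(5000))
    expect_lt(abs(partial_correlation(d2, "x", "z", response = "y")), 0.05)
    # degenerate residuals
    d3 <- data.frame(x = rnorm(30))
    d3$t <- 2 * d3$x
    d3$y <- rnorm(30)
    expect_error(partial_correlation(d3, "t", "x", response = "y"),
                 "degenerate")
  })
})

test_that("planted coefficients are recovered within 2 SE most of the time", {
  withr::with_seed(25, {
    hits <- vapply(1:120, function(i) {
      n <- 300
      d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
      d$y <- 1 + 0.7 * d$x1 - 0.4 * d$x2 + rnorm(n)
      fit <- fit_ols(d, c("x1", "x2"), response = "y")
      cf <- fit$coefficients
      all(abs(cf$estimate - c(1, 0.7, -0.4)) <= 2 * cf$std_error)
    }, logical(1))
    # joint coverage of three intervals at ~95% each
    expect_gt(mean(hits), 0.80)
  })
})
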