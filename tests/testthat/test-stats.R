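# direct likelihood-maximization oracle for small logistic problems
oracle_logistic <- function(X, y) {
  nll <- function(b) {
    eta <- as.numeric(X %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  stats::optim(rep(0, ncol(X)), nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))$par
}

test_that("2x2 odds ratio basics and the swap identity", {
  # equal case fractions in both groups
  expect_equal(odds_ratio_2x2(20, 80, 10, 40)$or, 1)
  a <- odds_ratio_2x2(30, 70, 15, 85)
  b <- odds_ratio_2x2(15, 85, 30, 70)
  expect_equal(a$or, 1 / b$or, tolerance = 1e-12)
  expect_equal(a$ci_low, 1 / b$ci_high, tolerance = 1e-12)
  expect_equal(a$ci_high, 1 / b$ci_low, tolerance = 1e-12)
  expect_error(odds_ratio_2x2(0, 10, 5, 5), "zero cell")
})

test_that("logistic fit on collapsed 2x2 data equals the closed-form OR", {
  a <- 37; b <- 63; c_ <- 21; d <- 79
  df <- data.frame(
    y = rep(c(1, 0, 1, 0), c(a, b, c_, d)),
    g = rep(c("exposed", "ref"), c(a + b, c_ + d)))
  fit <- fit_logistic(df, model_spec("y", categorical = list(g = "ref")))
  or <- odds_ratio_2x2(a, b, c_, d)
  est <- odds_ratios(fit)
  expect_equal(unname(est[1, "or"]), or$or, tolerance = 1e-10)
  expect_equal(unname(est[1, "ci_low"]), or$ci_low, tolerance = 1e-10)
  expect_equal(unname(est[1, "ci_high"]), or$ci_high, tolerance = 1e-10)
})

test_that("IRLS coefficients match direct likelihood maximization", {
  # overlapping classes: no separation, finite MLE
  df <- data.frame(y = c(0, 0, 1, 0, 1, 1, 0, 1),
                   x1 = c(0.2, 2.1, 2.3, 0.4, 1.9, 0.6, 2.4, 1.5),
                   x2 = c(1, 0, 1, 0, 0, 1, 1, 0))
  fit <- fit_logistic(df, model_spec("y", continuous = c("x1", "x2")))
  X <- cbind(1, df$x1, df$x2)
  expect_equal(unname(fit$beta), oracle_logistic(X, df$y),
               tolerance = 1e-4)
})

test_that("missing covariate rows are dropped and counted", {
  df <- data.frame(y = rbinom(40, 1, 0.4), x = rnorm(40))
  df$x[c(3, 17)] <- NA
  fit <- fit_logistic(df, model_spec("y", continuous = "x"))
  expect_equal(fit$n_dropped, 2)
  expect_equal(fit$n, 38)
})

test_that("perfect separation is reported as an error", {
  df <- data.frame(y = c(rep(0, 10), rep(1, 10)),
                   x = c(rnorm(10, -5), rnorm(10, 5)))
  expect_error(fit_logistic(df, model_spec("y", continuous = "x")),
               "separation")
})

test_that("partial Wald chi-squared: single-df identity and 2-df oracle", {
  set.seed(8)
  df <- data.frame(y = rbinom(300, 1, 0.4), x = rnorm(300),
                   g = sample(c("a", "b", "c"), 300, replace = TRUE))
  fit <- fit_logistic(df, model_spec("y", continuous = "x",
                                     categorical = list(g = "a")))
  w <- wald_partial_chisq(fit)
  # 1-df block equals (beta/se)^2
  bx <- fit$beta["x"]
  sex <- sqrt(fit$vcov["x", "x"])
  expect_equal(w$chisq[w$variable == "x"], unname((bx / sex)^2),
               tolerance = 1e-10)
  # 2-df block: explicit matrix arithmetic
  idx <- grep("^g", names(fit$beta))
  b <- fit$beta[idx]
  V <- fit$vcov[idx, idx]
  det2 <- V[1, 1] * V[2, 2] - V[1, 2] * V[2, 1]
  Vinv <- matrix(c(V[2, 2], -V[2, 1], -V[1, 2], V[1, 1]), 2) / det2
  manual <- b[1]^2 * Vinv[1, 1] + 2 * b[1] * b[2] * Vinv[1, 2] +
    b[2]^2 * Vinv[2, 2]
  expect_equal(w$chisq[w$variable == "g"], unname(manual),
               tolerance = 1e-10)
  expect_equal(sum(w$share_pct), 100, tolerance = 1e-6)
  expect_equal(w$df[w$variable == "g"], 2)
  # shares invariant to covariate order in the model spec
  fit2 <- fit_logistic(df, model_spec("y", categorical = list(g = "a"),
                                      continuous = "x"))
  w2 <- wald_partial_chisq(fit2)
  expect_equal(w$chisq[match(w2$variable, w$variable)], w2$chisq,
               tolerance = 1e-8)
})

test_that("exact-linear Shapley: efficiency and the binary closed form", {
  set.seed(9)
  n <- 200
  df <- data.frame(y = rbinom(n, 1, 0.5),
                   x = rep(c(0, 1), each = n / 2),
                   z = rnorm(n))
  fit <- fit_logistic(df, model_spec("y", continuous = c("x", "z")))
  sh <- shapley_importance(fit)
  phi <- attr(sh, "phi")
  X <- stats::model.matrix(fit$glm)
  eta <- as.numeric(X %*% fit$beta)
  expect_equal(unname(rowSums(phi)), unname(eta - mean(eta)),
               tolerance = 1e-9)
  # binary covariate at prevalence 0.5: |x - xbar| = 0.5 for every row
  expect_equal(unname(sh$mean_abs_shapley[sh$variable == "x"]),
               abs(fit$beta[["x"]]) * 0.5, tolerance = 1e-10)
})

test_that("exact-linear Shapley equals brute-force permutation enumeration", {
  set.seed(10)
  n <- 60
  df <- data.frame(y = rbinom(n, 1, 0.5), a = rnorm(n),
                   b = rnorm(n), g = sample(c("u", "v"), n, replace = TRUE))
  fit <- fit_logistic(df, model_spec("y", continuous = c("a", "b"),
                                     categorical = list(g = "u")))
  sh <- shapley_importance(fit)
  phi <- attr(sh, "phi")
  # enumerate all 3! orderings of the three variables; value of a coalition
  # = linear predictor with excluded variables held at their means
  X <- stats::model.matrix(fit$glm)
  xbar <- colMeans(X)
  groups <- lapply(1:3, function(i) which(fit$assign == i))
  vfun <- function(S, i) {
    xx <- xbar
    for (j in S) xx[groups[[j]]] <- X[i, groups[[j]]]
    sum(xx * fit$beta)
  }
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  for (i in c(1, 17, 42)) {
    brute <- numeric(3)
    for (p in perms) {
      S <- integer(0)
      for (j in p) {
        brute[j] <- brute[j] + vfun(c(S, j), i) - vfun(S, i)
        S <- c(S, j)
      }
    }
    brute <- brute / length(perms)
    expect_equal(unname(phi[i, ]), brute, tolerance = 1e-9)
  }
})

test_that("montecarlo Shapley agrees with the exact mode and guards m", {
  set.seed(11)
  df <- data.frame(y = rbinom(100, 1, 0.5), a = rnorm(100), b = rnorm(100))
  fit <- fit_logistic(df, model_spec("y", continuous = c("a", "b")))
  ex <- shapley_importance(fit, mode = "exact_linear")
  mc <- shapley_importance(fit, mode = "montecarlo", m = 50, seed = 4)
  expect_equal(mc$mean_abs_shapley, ex$mean_abs_shapley, tolerance = 1e-9)
  expect_error(shapley_importance(fit, mode = "montecarlo", m = 5),
               "m >= 10")
})

test_that("pseudo-R2: null model gives zero, toys match the formulas", {
  set.seed(12)
  df <- data.frame(y = rbinom(60, 1, 0.5), x = rnorm(60))
  null_fit <- fit_logistic(df, model_spec("y"))
  r0 <- pseudo_r2(null_fit)
  expect_equal(r0$mcfadden, 0, tolerance = 1e-10)
  expect_equal(r0$nagelkerke, 0, tolerance = 1e-10)

  df2 <- data.frame(y = c(0, 0, 1, 1, 0, 1, 1, 0, 0, 1),
                    x = c(0.1, 1.4, 0.9, 1.6, 0.7, 2.1, 0.8, 2.4, 0.2,
                          1.2))
  fit <- fit_logistic(df2, model_spec("y", continuous = "x"))
  # independent likelihood evaluation at the fitted and null optimum
  p <- stats::plogis(fit$beta[1] + fit$beta[2] * df2$x)
  ll <- sum(df2$y * log(p) + (1 - df2$y) * log(1 - p))
  pbar <- mean(df2$y)
  ll0 <- sum(df2$y * log(pbar) + (1 - df2$y) * log(1 - pbar))
  expect_equal(fit$loglik, ll, tolerance = 1e-8)
  expect_equal(fit$null_loglik, ll0, tolerance = 1e-8)
  r <- pseudo_r2(fit)
  expect_equal(r$mcfadden, 1 - ll / ll0, tolerance = 1e-8)
  cs <- 1 - exp(2 * (ll0 - ll) / 10)
  expect_equal(r$cox_snell, cs, tolerance = 1e-8)
  expect_equal(r$nagelkerke, cs / (1 - exp(2 * ll0 / 10)),
               tolerance = 1e-8)
  expect_gte(r$nagelkerke, r$cox_snell)
  expect_true(r$mcfadden >= 0 && r$mcfadden < 1)
})
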