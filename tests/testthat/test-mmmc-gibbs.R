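fake_result <- function(beta, sigma2, deviance = numeric(0),
                        dev_at_mean = NA_real_) {
  structure(list(beta = beta, sigma2 = sigma2, deviance = deviance,
                 dev_at_mean = dev_at_mean,
                 ess = rep(nrow(beta), ncol(beta) + ncol(sigma2))),
            class = "mcmc_result")
}

test_that("with no random structure the sampler collapses to OLS", {
  set.seed(900)
  n <- 500
  X <- cbind(1, stats::rnorm(n))
  y <- drop(X %*% c(1, 0.5)) + stats::rnorm(n)   # all random-effect variances 0
  school <- build_weight_matrix(
    classification_from_factor(factor(rep(1:10, each = 50)),
                               as.character(1:n), "school"), "equal")
  fit <- fit_mmmc(mmmc_spec(list(school = school), chain = 1500, burnin = 300,
                            seed = 2), y, X)
  ols <- stats::lm.fit(X, y)$coefficients
  mcse <- apply(fit$beta, 2, stats::sd) / sqrt(pmax(fit$ess[1:2], 1))
  # posterior mean within 3 Monte-Carlo SEs plus sampling noise of OLS
  expect_true(all(abs(fit$beta_mean - ols) <
                    3 * (mcse + apply(fit$beta, 2, stats::sd))))
  expect_lt(fit$sigma2_mean[["school"]], 0.1)
})

test_that("with variances fixed at truth the beta posterior matches the conjugate closed form", {
  set.seed(31)
  n <- 120
  school_f <- factor(rep(1:8, each = 15))
  Z <- build_weight_matrix(classification_from_factor(school_f, as.character(1:n)),
                           "equal")
  X <- cbind(1, stats::rnorm(n), stats::rbinom(n, 1, 0.5))
  u <- stats::rnorm(8, 0, sqrt(0.3))
  y <- drop(X %*% c(0, 0.4, -0.2)) + u[school_f] + stats::rnorm(n, 0, sqrt(0.8))
  fit <- fit_mmmc(mmmc_spec(list(school = Z), chain = 4000, burnin = 500,
                            seed = 5,
                            fix_variances = c(school = 0.3, individual = 0.8)),
                  y, X)
  oracle <- conjugate_beta_posterior(y, X, list(wm_matrix(Z)), 0.3, 0.8)
  mcse <- apply(fit$beta, 2, stats::sd) / sqrt(pmax(fit$ess[1:3], 2))
  expect_true(all(abs(fit$beta_mean - oracle$mean) < 3 * mcse))
  got_cov <- stats::cov(fit$beta)
  expect_true(all(abs(got_cov - oracle$cov) < 0.3 * abs(diag(oracle$cov)) %o%
                    rep(1, 3) + 3e-4))
  # fixed variances really are fixed
  expect_true(all(fit$sigma2[, "school"] == 0.3))
  expect_true(all(fit$sigma2[, "individual"] == 0.8))
})

test_that("chains are bit-identical under a repeated seed", {
  set.seed(8)
  n <- 80
  X <- cbind(1, stats::rnorm(n))
  net <- random_directed_net(n, 0.04, ids = as.character(1:n))
  eg <- build_weight_matrix(classification_from_egonets(net), "equal")
  y <- stats::rnorm(n)
  spec <- mmmc_spec(list(egonet = eg), chain = 400, burnin = 100, seed = 77)
  f1 <- fit_mmmc(spec, y, X)
  f2 <- fit_mmmc(spec, y, X)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$sigma2, f2$sigma2)
  expect_identical(f1$u_mean, f2$u_mean)
})

test_that("joint and single-site updates agree in the posterior", {
  set.seed(14)
  n <- 60
  X <- cbind(1, stats::rnorm(n))
  g <- factor(sample(1:6, n, replace = TRUE))
  Z <- build_weight_matrix(classification_from_factor(g, as.character(1:n)), "equal")
  y <- drop(X %*% c(0.3, 0.5)) + stats::rnorm(6, 0, 0.6)[g] + stats::rnorm(n)
  fj <- fit_mmmc(mmmc_spec(list(g = Z), chain = 4000, burnin = 1000, seed = 3,
                           update = "joint"), y, X)
  fs <- fit_mmmc(mmmc_spec(list(g = Z), chain = 4000, burnin = 1000, seed = 4,
                           update = "single"), y, X)
  tol <- 3 * (apply(fj$beta, 2, stats::sd) / sqrt(pmax(fj$ess[1:2], 2)) +
              apply(fs$beta, 2, stats::sd) / sqrt(pmax(fs$ess[1:2], 2)))
  expect_true(all(abs(fj$beta_mean - fs$beta_mean) < tol))
  expect_lt(abs(fj$sigma2_mean[["individual"]] - fs$sigma2_mean[["individual"]]),
            0.15)
})

test_that("exchanging labels of two identical classifications leaves beta and sigma2_e invariant", {
  set.seed(21)
  n <- 70
  X <- cbind(1, stats::rnorm(n))
  g <- factor(sample(1:5, n, replace = TRUE))
  Z <- build_weight_matrix(classification_from_factor(g, as.character(1:n)), "equal")
  y <- stats::rnorm(n)
  fa <- fit_mmmc(mmmc_spec(list(a = Z, b = Z), chain = 600, burnin = 100,
                           seed = 9), y, X)
  fb <- fit_mmmc(mmmc_spec(list(b = Z, a = Z), chain = 600, burnin = 100,
                           seed = 9), y, X)
  expect_identical(fa$beta, fb$beta)
  expect_identical(fa$sigma2[, "individual"], fb$sigma2[, "individual"])
})

test_that("input validation: rank deficiency, zero weights, dimensions", {
  y <- stats::rnorm(20)
  Xbad <- cbind(1, 1:20, 2 * (1:20))
  expect_error(fit_mmmc(mmmc_spec(), y, Xbad), "rank deficient")
  Wz <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                             dims = c(20, 3))
  expect_warning(fit_mmmc(mmmc_spec(list(z = Wz), chain = 200, burnin = 50,
                                    seed = 1), y, cbind(rep(1, 20))),
                 "all-zero")
  expect_error(fit_mmmc(mmmc_spec(list(z = Wz[1:10, ]), chain = 200,
                                  burnin = 50, seed = 1), y, cbind(rep(1, 20))),
               "row count")
})

test_that("DIC bookkeeping: degenerate chains give pD = 0", {
  res <- fake_result(beta = matrix(1, 5, 1), sigma2 = matrix(2, 5, 1,
                     dimnames = list(NULL, "individual")),
                     deviance = rep(123.4, 5), dev_at_mean = 123.4)
  d <- dic(res)
  expect_equal(unname(d["pD"]), 0)
  expect_equal(unname(d["DIC"]), 123.4)
  expect_error(dic(fake_result(matrix(1, 0, 1),
                               matrix(1, 0, 1, dimnames = list(NULL, "individual")))),
               "empty chain")
})

test_that("posterior summaries recompute directly from the stored draws", {
  beta <- matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "b0"))
  sg <- matrix(c(0.5, 1, 1.5), 3, 1, dimnames = list(NULL, "individual"))
  res <- fake_result(beta, sg)
  tab <- posterior_summary(res)
  expect_equal(tab$mean[tab$parameter == "b0"], 2)
  expect_equal(tab$sd[tab$parameter == "b0"], 1)

  # quantiles match an order-statistics computation on a real chain
  set.seed(4)
  n <- 50
  X <- cbind(rep(1, n))
  fit <- fit_mmmc(mmmc_spec(chain = 800, burnin = 200, seed = 6),
                  stats::rnorm(n), X)
  tab2 <- posterior_summary(fit)
  chain <- sort(fit$beta[, 1])
  qs <- stats::quantile(chain, c(0.025, 0.975), names = FALSE)
  expect_equal(tab2$q2.5[1], qs[1])
  expect_equal(tab2$q97.5[1], qs[2])
  expect_equal(tab2$mean[1], mean(fit$beta[, 1]))
})
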