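#' Specify an MMMC model
#'
#' An MMMC (multiple-membership multiple-classification) model for a
#' continuous response is
#' \deqn{y_i = x_i'\beta + \sum_k \sum_{j \in k(i)} w^{(k)}_{ij} u^{(k)}_j + e_i,}
#' with one set of random effects \eqn{u^{(k)} \sim N(0, \sigma^2_k I)} per
#' classification (ego-nets, dyads, cliques, schools, areas, ...), weights
#' given by the classification's weight matrix, and individual-level
#' residuals \eqn{e_i \sim N(0, \sigma^2_e)}. Random effects are a priori
#' independent across classifications. Estimation is by Gibbs sampling with
#' flat priors on the fixed effects and diffuse Gamma(`prior_shape`,
#' `prior_rate`) priors on each precision.
#'
#' @param classifications named list of `weight_matrix` objects (or bare
#'   matrices), all with n rows. May be empty (single-level model).
#' @param chain total number of MCMC iterations (default 20000).
#' @param burnin iterations discarded (default 2000).
#' @param thin keep every `thin`-th retained draw.
#' @param seed RNG seed; identical spec + seed reproduce chains exactly.
#' @param prior_shape,prior_rate Gamma prior on precisions (default
#'   0.001, 0.001, the conventional diffuse choice).
#' @param fix_variances optional named numeric vector of variance components
#'   to hold fixed instead of sampling; use classification names and/or
#'   `"individual"` for \eqn{\sigma^2_e}.
#' @param update `"joint"` (default): each classification's random-effect
#'   block is drawn jointly from its multivariate conditional via a sparse
#'   Cholesky factorisation; `"single"`: one effect at a time (slower,
#'   provided as a cross-check).
#' @return object of class `mmmc_spec`.
#' @export
mmmc_spec <- function(classifications = list(), chain = 20000, burnin = 2000,
                      thin = 1, seed = 1, prior_shape = 0.001,
                      prior_rate = 0.001, fix_variances = NULL,
                      update = c("joint", "single")) {
  update <- match.arg(update)
  if (length(classifications)) {
    if (is.null(names(classifications)) || any(!nzchar(names(classifications))))
      stop("classifications must be a named list")
    if (anyDuplicated(names(classifications)))
      stop("classification names must be unique")
  }
  stopifnot(chain > burnin, burnin >= 0, thin >= 1)
  structure(list(classifications = classifications, chain = as.integer(chain),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 seed = as.integer(seed), prior_shape = prior_shape,
                 prior_rate = prior_rate, fix_variances = fix_variances,
                 update = update),
            class = "mmmc_spec")
}

#' Fit an MMMC model by Gibbs sampling
#'
#' Each sweep draws, in order: the fixed effects \eqn{\beta} from their
#' conditional Normal (flat prior; mean the OLS fit of the current partial
#' residual, covariance \eqn{\sigma^2_e (X'X)^{-1}}); each classification's
#' random-effect vector jointly from a Normal with sparse precision
#' \eqn{Z_k'Z_k/\sigma^2_e + I/\sigma^2_k}; each precision
#' \eqn{1/\sigma^2_k} from its conditional Gamma; and the residual
#' precision \eqn{1/\sigma^2_e} from its conditional Gamma. Effect columns
#' that no individual loads on (e.g. never-nominated individuals in the
#' ego-net classification) are dropped before sampling: they carry no
#' information and would only slow the variance-component mixing.
#'
#' @param spec an [mmmc_spec()].
#' @param y numeric response vector (finite).
#' @param X fixed-effects design matrix including the intercept column;
#'   must be full column rank.
#' @return object of class `mcmc_result`: retained chains for `beta`
#'   (draws x p), `sigma2` (draws x (K+1), last column `individual`),
#'   `deviance`; posterior means `beta_mean`, `sigma2_mean`, `u_mean` /
#'   `u_sd` per classification; `dic`, `pd`; `ess` per stored chain; the
#'   spec and seed.
#' @export
fit_mmmc <- function(spec, y, X) {
  stopifnot(inherits(spec, "mmmc_spec"))
  y <- as.numeric(y)
  n <- length(y)
  if (!all(is.finite(y))) stop("response must be finite")
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  p <- ncol(X)
  if (n < p) stop("need n >= p")
  if (qr(X)$rank < p) stop("fixed design matrix is rank deficient")
  cls_names <- names(spec$classifications)
  ncls <- length(spec$classifications)

  # per-classification precomputation
  Zs <- list(); keeps <- list(); ZtZs <- list(); Ch0s <- list(); Kfull <- integer(ncls)
  for (k in seq_len(ncls)) {
    Z <- wm_matrix(spec$classifications[[k]])
    if (nrow(Z) != n) stop("weight matrix '", cls_names[k], "' has wrong row count")
    Kfull[k] <- ncol(Z)
    if (all(Z@x == 0) || length(Z@x) == 0) {
      warning("classification '", cls_names[k],
              "' has an all-zero weight matrix and contributes nothing")
    }
    keep <- which(Matrix::colSums(Z != 0) > 0)
    Zk <- Z[, keep, drop = FALSE]
    ZtZ <- Matrix::forceSymmetric(Matrix::crossprod(Zk))
    Zs[[k]] <- Zk; keeps[[k]] <- keep; ZtZs[[k]] <- ZtZ
    Ch0s[[k]] <- if (length(keep))
      Matrix::Cholesky(ZtZ, Imult = 1, LDL = FALSE, perm = TRUE) else NULL
  }

  a <- spec$prior_shape; b <- spec$prior_rate
  fixv <- spec$fix_variances
  is_fixed <- function(nm) !is.null(fixv) && nm %in% names(fixv)

  set.seed(spec$seed)
  # initial values: beta at OLS, variances an equal split of var(y)
  qrX <- qr(X)
  XtX <- crossprod(X)
  Rx <- chol(XtX)
  beta <- qr.coef(qrX, y)
  v0 <- stats::var(y) / (ncls + 1)
  sig2 <- rep(v0, ncls)
  names(sig2) <- cls_names
  sig2e <- v0
  for (k in seq_len(ncls)) if (is_fixed(cls_names[k])) sig2[k] <- fixv[[cls_names[k]]]
  if (is_fixed("individual")) sig2e <- fixv[["individual"]]
  u <- lapply(seq_len(ncls), function(k) numeric(length(keeps[[k]])))
  zu <- lapply(seq_len(ncls), function(k) numeric(n))   # Z_k u_k, kept current
  fitted_random <- numeric(n)

  n_ret <- (spec$chain - spec$burnin) %/% spec$thin
  beta_draws <- matrix(NA_real_, n_ret, p, dimnames = list(NULL, colnames(X)))
  sig2_draws <- matrix(NA_real_, n_ret, ncls + 1,
                       dimnames = list(NULL, c(cls_names, "individual")))
  dev_draws <- numeric(n_ret)
  u_sum <- lapply(u, function(z) numeric(length(z)))
  u_sumsq <- lapply(u, function(z) numeric(length(z)))
  r <- 0L

  for (it in seq_len(spec$chain)) {
    # (i) beta | rest
    resid0 <- y - fitted_random
    bhat <- backsolve(Rx, backsolve(Rx, crossprod(X, resid0), transpose = TRUE))
    beta <- drop(bhat) + sqrt(sig2e) * backsolve(Rx, stats::rnorm(p))
    xb <- drop(X %*% beta)

    # (ii) random effects per classification
    for (k in seq_len(ncls)) {
      Kk <- length(keeps[[k]])
      if (Kk == 0) next
      rk <- y - xb - (fitted_random - zu[[k]])
      if (spec$update == "joint") {
        Ch <- Matrix::update(Ch0s[[k]], ZtZs[[k]] * (1 / sig2e), mult = 1 / sig2[k])
        bvec <- Matrix::crossprod(Zs[[k]], rk) / sig2e
        mu_k <- Matrix::solve(Ch, bvec, system = "A")
        zdev <- Matrix::solve(Ch, Matrix::solve(
          Ch, stats::rnorm(Kk), system = "Lt"), system = "Pt")
        u[[k]] <- as_num(mu_k) + as_num(zdev)
      } else {
        u[[k]] <- single_site_update(Zs[[k]], u[[k]], rk, sig2e, sig2[k])
      }
      zu[[k]] <- as_num(Zs[[k]] %*% u[[k]])
      fitted_random <- (y - xb - rk) + zu[[k]]
    }

    # (iii) classification variances: conditional Gamma draw, then an
    # ancillarity-sufficiency (interweaving) rescaling of (u_k, sigma_k)
    # jointly, which breaks the strong u--sigma^2 coupling that otherwise
    # makes weakly identified network variance components mix very slowly
    for (k in seq_len(ncls)) {
      if (is_fixed(cls_names[k])) next
      Kk <- length(keeps[[k]])
      if (Kk == 0) next
      sig2[k] <- 1 / stats::rgamma(1, a + Kk / 2, b + sum(u[[k]]^2) / 2)
      sig_cur <- sqrt(sig2[k])
      if (sig_cur > 0 && any(zu[[k]] != 0)) {
        v <- zu[[k]] / sig_cur                 # non-centered: Z (u / sigma)
        rk <- y - xb - (fitted_random - zu[[k]])
        sv2 <- sum(v^2); svr <- sum(v * rk)
        lpost <- function(s) {
          es <- exp(s)
          -es^2 * sv2 / (2 * sig2e) + es * svr / sig2e - 2 * a * s -
            b * exp(-2 * s)
        }
        s_new <- slice_sample_1d(log(sig_cur), lpost)
        ratio <- exp(s_new) / sig_cur
        u[[k]] <- u[[k]] * ratio
        fitted_random <- fitted_random + (ratio - 1) * zu[[k]]
        zu[[k]] <- zu[[k]] * ratio
        sig2[k] <- exp(2 * s_new)
      }
    }

    # (iv) residual variance
    ssr <- sum((y - xb - fitted_random)^2)
    if (!is_fixed("individual")) {
      sig2e <- 1 / stats::rgamma(1, a + n / 2, b + ssr / 2)
    }

    if (it > spec$burnin && (it - spec$burnin) %% spec$thin == 0) {
      r <- r + 1L
      beta_draws[r, ] <- beta
      sig2_draws[r, ] <- c(sig2, sig2e)
      dev_draws[r] <- n * log(2 * pi * sig2e) + ssr / sig2e
      for (k in seq_len(ncls)) {
        u_sum[[k]] <- u_sum[[k]] + u[[k]]
        u_sumsq[[k]] <- u_sumsq[[k]] + u[[k]]^2
      }
    }
  }

  u_mean <- vector("list", ncls); u_sd <- vector("list", ncls)
  names(u_mean) <- cls_names; names(u_sd) <- cls_names
  for (k in seq_len(ncls)) {
    m_full <- numeric(Kfull[k]); s_full <- numeric(Kfull[k])
    m <- u_sum[[k]] / n_ret
    v <- pmax(u_sumsq[[k]] / n_ret - m^2, 0)
    m_full[keeps[[k]]] <- m
    s_full[keeps[[k]]] <- sqrt(v)
    cn <- colnames(wm_matrix(spec$classifications[[k]]))
    if (!is.null(cn)) { names(m_full) <- cn; names(s_full) <- cn }
    u_mean[[k]] <- m_full; u_sd[[k]] <- s_full
  }

  beta_mean <- colMeans(beta_draws)
  sigma2_mean <- colMeans(sig2_draws)
  mu_bar <- drop(X %*% beta_mean)
  for (k in seq_len(ncls)) {
    mu_bar <- mu_bar + as_num(Zs[[k]] %*% (u_mean[[k]][keeps[[k]]]))
  }
  dev_at_mean <- gaussian_deviance(y, mu_bar, sigma2_mean[["individual"]])
  dbar <- mean(dev_draws)
  res <- structure(list(
    beta = beta_draws, sigma2 = sig2_draws, deviance = dev_draws,
    beta_mean = beta_mean, sigma2_mean = sigma2_mean,
    u_mean = u_mean, u_sd = u_sd,
    dev_at_mean = dev_at_mean,
    dic = 2 * dbar - dev_at_mean, pd = dbar - dev_at_mean,
    ess = c(apply(beta_draws, 2, ess_chain),
            stats::setNames(apply(sig2_draws, 2, ess_chain),
                            paste0("sigma2_", colnames(sig2_draws)))),
    n = n, p = p, spec = spec, seed = spec$seed
  ), class = "mcmc_result")
  res
}

# Univariate slice sampler (stepping out, Neal 2003) on an unnormalised
# log-density; used for the interweaving scale move.
slice_sample_1d <- function(x0, logf, w = 1, max_steps = 50) {
  logy <- logf(x0) - stats::rexp(1)
  L <- x0 - w * stats::runif(1)
  R <- L + w
  j <- floor(max_steps * stats::runif(1))
  kk <- (max_steps - 1) - j
  while (j > 0 && logf(L) > logy) { L <- L - w; j <- j - 1 }
  while (kk > 0 && logf(R) > logy) { R <- R + w; kk <- kk - 1 }
  repeat {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) > logy) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}

# One-at-a-time Gauss-Seidel-style update of a random-effect block;
# equivalent stationary distribution to the joint draw, used as a
# cross-check. rk is the partial residual excluding this block.
single_site_update <- function(Z, u, rk, sig2e, sig2k) {
  Zc <- methods::as(Z, "CsparseMatrix")
  pp <- Zc@p; ii <- Zc@i; xx <- Zc@x
  resid <- rk - as_num(Z %*% u)   # full residual including this block
  for (j in seq_along(u)) {
    sel <- seq.int(pp[j] + 1L, length.out = pp[j + 1L] - pp[j])
    rows <- ii[sel] + 1L
    w <- xx[sel]
    resid[rows] <- resid[rows] + w * u[j]       # remove effect j
    prec <- sum(w^2) / sig2e + 1 / sig2k
    mean_j <- sum(w * resid[rows]) / sig2e / prec
    u[j] <- stats::rnorm(1, mean_j, sqrt(1 / prec))
    resid[rows] <- resid[rows] - w * u[j]
  }
  u
}

#' @export
print.mcmc_result <- function(x, ...) {
  cat(sprintf("mcmc_result: %d retained draws, n = %d\n", nrow(x$beta), x$n))
  cat(sprintf("  DIC = %.1f, pD = %.1f\n", x$dic, x$pd))
  print(posterior_summary(x), digits = 3)
  invisible(x)
}

#' Deviance information criterion of a fitted MMMC model
#'
#' `DIC = 2 * mean(D) - D(theta_bar)` where the deviance
#' `D = n log(2 pi sigma2_e) + SSR / sigma2_e` uses the full fitted mean
#' (fixed part plus all weighted random effects) and the plug-in
#' `D(theta_bar)` evaluates posterior means of all parameters, including
#' the random effects. `pD = mean(D) - D(theta_bar)` estimates the
#' effective number of parameters.
#'
#' @param result an `mcmc_result`.
#' @return named numeric vector `c(DIC = , pD = )`.
#' @export
dic <- function(result) {
  stopifnot(inherits(result, "mcmc_result"))
  if (!length(result$deviance)) stop("empty chain: no retained draws")
  dbar <- mean(result$deviance)
  c(DIC = 2 * dbar - result$dev_at_mean, pD = dbar - result$dev_at_mean)
}

#' Posterior summary table
#'
#' One row per fixed coefficient and variance component: posterior mean,
#' SD, central 95% interval and effective sample size. Random effects are
#' summarised only on request.
#'
#' @param result an `mcmc_result`.
#' @param include_random also append rows for individual random effects
#'   (posterior mean and SD; intervals and ESS not stored for these).
#' @return a `data.frame` with columns `parameter`, `mean`, `sd`, `q2.5`,
#'   `q97.5`, `ess`.
#' @export
posterior_summary <- function(result, include_random = FALSE) {
  stopifnot(inherits(result, "mcmc_result"))
  chains <- cbind(result$beta, result$sigma2)
  colnames(chains) <- c(colnames(result$beta),
                        paste0("sigma2_", colnames(result$sigma2)))
  qs <- t(apply(chains, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE))
  out <- data.frame(parameter = colnames(chains),
                    mean = colMeans(chains),
                    sd = apply(chains, 2, stats::sd),
                    q2.5 = qs[, 1], q97.5 = qs[, 2],
                    ess = unname(result$ess[seq_len(ncol(chains))]),
                    row.names = NULL)
  if (include_random) {
    for (k in names(result$u_mean)) {
      um <- result$u_mean[[k]]
      nm <- if (is.null(names(um))) paste0(k, "[", seq_along(um), "]")
            else paste0(k, "[", names(um), "]")
      out <- rbind(out, data.frame(parameter = nm, mean = um,
                                   sd = result$u_sd[[k]],
                                   q2.5 = NA_real_, q97.5 = NA_real_,
                                   ess = NA_real_, row.names = NULL))
    }
  }
  out
}
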