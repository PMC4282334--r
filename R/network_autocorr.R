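#' Log-likelihood of a network autocorrelation model
#'
#' Three Gaussian models with a row-standardized connection matrix `W`:
#' the *network effects* model \eqn{(I - \rho_1 W_1) y = X\beta + \epsilon}
#' (autoregression in the response, the spatial-lag analogue); the
#' *network disturbances* model \eqn{y = X\beta + \delta},
#' \eqn{\delta = \rho_2 W_2 \delta + \epsilon} (autoregression in the
#' error, the spatial-error analogue); and their combination with both
#' transforms. With \eqn{\epsilon \sim N(0, \sigma^2 I)} the log-likelihood
#' is \deqn{-\tfrac{n}{2}\log(2\pi\sigma^2) + \log|I-\rho_1 W_1| +
#' \log|I-\rho_2 W_2| - \tfrac{1}{2\sigma^2}\lVert r \rVert^2,}
#' with the residual \eqn{r} given by the model's transform and absent
#' Jacobian terms dropped. At \eqn{\rho = 0} (or `W = 0`) every model
#' reduces exactly to the OLS Gaussian log-likelihood.
#'
#' @param model `"effects"`, `"disturbances"` or `"combined"`.
#' @param rho autocorrelation parameter(s): scalar for the one-parameter
#'   models, `c(rho1, rho2)` for `"combined"`.
#' @param beta fixed-effect coefficients.
#' @param sigma2 residual variance (> 0).
#' @param y,X response and design.
#' @param W1,W2 weight matrices (`weight_matrix` or bare); `W1` for the
#'   response transform, `W2` for the error transform.
#' @return log-likelihood value.
#' @export
loglik_nam <- function(model = c("effects", "disturbances", "combined"),
                       rho, beta, sigma2, y, X, W1 = NULL, W2 = NULL) {
  model <- match.arg(model)
  y <- as.numeric(y); X <- as.matrix(X); n <- length(y)
  stopifnot(sigma2 > 0)
  rr <- nam_rho(model, rho)
  ld <- 0
  r <- y
  if (model %in% c("effects", "combined")) {
    A1 <- nam_transform(n, rr[1], W1, "rho1")
    ld <- ld + A1$logdet
    r <- A1$apply(r)
  }
  r <- r - drop(X %*% beta)
  if (model %in% c("disturbances", "combined")) {
    A2 <- nam_transform(n, rr[2], W2, "rho2")
    ld <- ld + A2$logdet
    r <- A2$apply(r)
  }
  -n / 2 * log(2 * pi * sigma2) + ld - sum(r^2) / (2 * sigma2)
}

nam_rho <- function(model, rho) {
  if (model == "combined") {
    if (length(rho) != 2) stop("combined model needs rho = c(rho1, rho2)")
    rho
  } else {
    if (length(rho) != 1) stop("one autocorrelation parameter expected")
    if (model == "effects") c(rho, 0) else c(0, rho)
  }
}

# I - rho*W with its log|det|; errors if the determinant is not positive.
nam_transform <- function(n, rho, W, label) {
  if (is.null(W)) stop("weight matrix required for ", label)
  W <- wm_matrix(W)
  stopifnot(nrow(W) == n, ncol(W) == n)
  if (rho == 0 || length(W@x) == 0) {
    return(list(logdet = 0, apply = function(v) v))
  }
  A <- Matrix::Diagonal(n) - rho * W
  dt <- Matrix::determinant(A, logarithm = TRUE)
  if (!is.finite(dt$modulus) || dt$sign <= 0) {
    stop(sprintf("I - rho*W is singular or has non-positive determinant at rho = %g", rho))
  }
  list(logdet = as.numeric(dt$modulus), apply = function(v) as_num(A %*% v))
}

#' Fit a network autocorrelation model by maximum likelihood
#'
#' `beta` and `sigma2` are profiled out analytically (OLS of the
#' transformed response for the effects model; GLS given `rho` for the
#' disturbances model; ML `sigma2 = RSS/n`), and the profile likelihood is
#' maximised over `rho` in the open interval (-1, 1) -- the admissible
#' region for a row-standardized `W`, whose eigenvalues have modulus at
#' most 1 -- by a coarse grid followed by golden-section refinement. The
#' combined model starts from the two one-parameter fits and optimises
#' `(rho1, rho2)` jointly by L-BFGS-B. Standard errors come from the
#' inverse numerical observed information of the full
#' `(rho, beta, sigma2)` log-likelihood at the optimum.
#'
#' @param y,X response and full-rank design (n > p).
#' @param W1,W2 weight matrices; `W2` defaults to `W1` (and vice versa)
#'   where the model needs both or the other one.
#' @param model `"effects"`, `"disturbances"` or `"combined"`.
#' @param rho_limit half-width of the search interval (default 1).
#' @return object of class `nam_fit`: `model`, `rho` (named), `rho_se`,
#'   `beta`, `beta_se`, `sigma2` (ML), `sigma2_df` (df-corrected
#'   alternative), `loglik`, `aic` (`2k - 2 loglik`, `k = p + #rho + 1`),
#'   `boundary` flag, `n`, `p`.
#' @export
fit_nam <- function(y, X, W1 = NULL, W2 = NULL,
                    model = c("effects", "disturbances", "combined"),
                    rho_limit = 1) {
  model <- match.arg(model)
  y <- as.numeric(y); X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y); p <- ncol(X)
  stopifnot(n > p)
  if (qr(X)$rank < p) stop("design matrix is rank deficient")
  if (is.null(W1)) W1 <- W2
  if (is.null(W2)) W2 <- W1
  if (is.null(W1)) stop("a weight matrix is required")
  W1 <- wm_matrix(W1); W2 <- wm_matrix(W2)
  eps <- 1e-7
  lo <- -rho_limit + eps; hi <- rho_limit - eps

  profile <- function(rho2) nam_profile(model, rho2, y, X, W1, W2)

  if (model == "combined") {
    f1 <- fit_nam(y, X, W1 = W1, model = "effects", rho_limit = rho_limit)
    f2 <- fit_nam(y, X, W2 = W2, model = "disturbances", rho_limit = rho_limit)
    start <- c(f1$rho[[1]], f2$rho[[1]])
    opt <- stats::optim(start, function(r) -profile(r)$loglik,
                        method = "L-BFGS-B", lower = c(lo, lo), upper = c(hi, hi))
    if (opt$convergence != 0) {
      stop("combined-model optimisation failed to converge: ", opt$message)
    }
    rho_hat <- opt$par
    names(rho_hat) <- c("rho1", "rho2")
  } else {
    grid <- seq(lo, hi, length.out = 81)
    gval <- vapply(grid, function(r) profile(r)$loglik, 0)
    i0 <- which.max(gval)
    bl <- grid[max(1, i0 - 1)]; bu <- grid[min(length(grid), i0 + 1)]
    opt <- stats::optimize(function(r) profile(r)$loglik, c(bl, bu),
                           maximum = TRUE, tol = 1e-9)
    rho_hat <- stats::setNames(opt$maximum,
                               if (model == "effects") "rho1" else "rho2")
  }
  prof <- profile(unname(rho_hat))
  boundary <- any(abs(abs(rho_hat) - rho_limit) < 1e-4)
  if (boundary) warning("rho estimate is at the boundary of the admissible interval")

  # observed information of the full (rho, beta, sigma2) likelihood
  theta <- c(rho_hat, prof$beta, sigma2 = prof$sigma2)
  nr <- length(rho_hat)
  nll <- function(th) {
    if (th[nr + p + 1] <= 0) return(1e10)
    -loglik_nam(model, th[seq_len(nr)], th[nr + seq_len(p)], th[nr + p + 1],
                y, X, W1 = W1, W2 = W2)
  }
  se <- rep(NA_real_, length(theta))
  vc <- try({
    H <- stats::optimHess(theta, nll)
    solve(H)
  }, silent = TRUE)
  if (!inherits(vc, "try-error") && all(diag(vc) > 0)) se <- sqrt(diag(vc))
  names(se) <- names(theta)

  k <- p + nr + 1
  structure(list(
    model = model, rho = rho_hat, rho_se = se[seq_len(nr)],
    beta = stats::setNames(prof$beta, colnames(X)),
    beta_se = stats::setNames(se[nr + seq_len(p)], colnames(X)),
    sigma2 = prof$sigma2, sigma2_df = prof$rss / (n - p),
    loglik = prof$loglik, aic = 2 * k - 2 * prof$loglik,
    boundary = boundary, n = n, p = p
  ), class = "nam_fit")
}

# profile likelihood pieces at a given rho (vector of 2 for combined)
nam_profile <- function(model, rho, y, X, W1, W2) {
  n <- length(y)
  rr <- nam_rho(model, rho)
  ld <- 0
  yt <- y; Xt <- X
  if (model %in% c("effects", "combined")) {
    A1 <- nam_transform(n, rr[1], W1, "rho1")
    ld <- ld + A1$logdet
    yt <- A1$apply(yt)
  }
  if (model %in% c("disturbances", "combined")) {
    A2 <- nam_transform(n, rr[2], W2, "rho2")
    ld <- ld + A2$logdet
    yt <- A2$apply(yt)
    Xt <- apply(X, 2, A2$apply)
  }
  fit <- stats::lm.fit(Xt, yt)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / n
  list(beta = fit$coefficients, sigma2 = sigma2, rss = rss,
       loglik = -n / 2 * log(2 * pi * sigma2) + ld - n / 2)
}

#' @export
print.nam_fit <- function(x, ...) {
  cat(sprintf("nam_fit (%s): n = %d, loglik = %.2f, AIC = %.1f\n",
              x$model, x$n, x$loglik, x$aic))
  for (i in seq_along(x$rho)) {
    cat(sprintf("  %s = %.3f (SE %.3f)\n", names(x$rho)[i], x$rho[i], x$rho_se[i]))
  }
  cat(sprintf("  sigma2 (ML) = %.3f\n", x$sigma2))
  tab <- data.frame(estimate = x$beta, se = x$beta_se)
  print(tab, digits = 3)
  invisible(x)
}
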