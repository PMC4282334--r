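#' Fit a grid of MMMC models over classification subsets
#'
#' Fits one MMMC model per requested subset of classifications -- e.g.
#' school only, network only, school + network, and the individual-only
#' (empty) model -- in the null (intercept-only) or covariate-adjusted
#' form, and tabulates variance components and DIC side by side. Every fit
#' uses the same seed, so any model also appears identically when fitted
#' standalone. A failed fit is recorded and the grid continues.
#'
#' @param y response vector.
#' @param X design matrix (use an intercept-only column for null models).
#' @param menu named list of character vectors; each element selects the
#'   classifications of one model (use `character(0)` for the
#'   individual-only model).
#' @param classifications named list of `weight_matrix` objects the menu
#'   draws from.
#' @param chain,burnin,thin,seed MCMC options passed to [mmmc_spec()].
#' @return object of class `mmmc_grid`: a `data.frame` with one row per
#'   model (`model`, `dic`, `pd`, one `sigma2_*` column per classification,
#'   `sigma2_individual`, `error`); fitted `mcmc_result`s in attribute
#'   `"fits"` and a reproducibility manifest in attribute `"manifest"`.
#' @export
run_model_grid <- function(y, X, menu, classifications,
                           chain = 5000, burnin = 1000, thin = 1, seed = 1) {
  stopifnot(is.list(menu), length(menu) >= 1)
  if (is.null(names(menu))) {
    names(menu) <- vapply(menu, function(m)
      if (length(m)) paste(m, collapse = "+") else "individual-only", "")
  }
  all_cls <- unique(unlist(menu))
  if (!all(all_cls %in% names(classifications))) {
    stop("menu requests unknown classification(s): ",
         paste(setdiff(all_cls, names(classifications)), collapse = ", "))
  }
  fits <- vector("list", length(menu))
  names(fits) <- names(menu)
  rows <- vector("list", length(menu))
  for (i in seq_along(menu)) {
    sel <- menu[[i]]
    res <- tryCatch(
      fit_mmmc(mmmc_spec(classifications[sel], chain = chain, burnin = burnin,
                         thin = thin, seed = seed), y, X),
      error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(model = names(menu)[i], dic = NA_real_,
                              pd = NA_real_, error = conditionMessage(res))
    } else {
      fits[[i]] <- res
      sg <- as.list(res$sigma2_mean)
      names(sg) <- paste0("sigma2_", names(sg))
      rows[[i]] <- cbind(data.frame(model = names(menu)[i], dic = res$dic,
                                    pd = res$pd),
                         as.data.frame(sg), data.frame(error = NA_character_))
    }
  }
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    r[setdiff(all_cols, names(r))] <- NA
    r[all_cols]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  attr(out, "manifest") <- list(seed = seed, chain = chain, burnin = burnin,
                                thin = thin, menu = menu,
                                n = length(y), p = ncol(as.matrix(X)))
  class(out) <- c("mmmc_grid", "data.frame")
  out
}

#' @export
print.mmmc_grid <- function(x, ...) {
  cat("MMMC model grid:\n")
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Compare the multiple-membership and network-disturbances models
#'
#' Head-to-head comparison on the same data and the same weight
#' information: a multiple-membership model with the ego-net
#' classification in the random part and fixed school indicator variables
#' (reference: first school level, so its dummy is absent and the
#' intercept is present), fitted by Gibbs sampling; and a network
#' disturbances model with the row-standardized nomination matrix, fitted
#' by maximum likelihood. Both models place the network in the random
#' (error) part, which is what makes them comparable.
#'
#' @param y response vector.
#' @param pop a `synthetic_population` (supplies network, school and
#'   covariates), or pass `school`, `net` and `X_cov` explicitly.
#' @param school factor of school memberships.
#' @param net a [directed_network()].
#' @param X_cov optional matrix of individual covariate columns (no
#'   intercept) to include alongside the school dummies; `NULL` fits the
#'   constant + school indicators model.
#' @param chain,burnin,seed MCMC options for the MM side.
#' @return object of class `mm_nd_comparison`: `coefficients`
#'   (data.frame: `term`, `est_mm`, `se_mm`, `est_nd`, `se_nd`), `mm`
#'   (`mcmc_result`), `nd` (`nam_fit`), `dic`, `aic`, `rho`, `rho_se`,
#'   manifest attribute.
#' @export
run_mm_vs_nd <- function(y, pop = NULL, school = NULL, net = NULL,
                         X_cov = NULL, chain = 5000, burnin = 1000, seed = 1) {
  if (!is.null(pop)) {
    stopifnot(inherits(pop, "synthetic_population"))
    school <- pop$covariates$school
    net <- pop$network
  }
  stopifnot(!is.null(school), inherits(net, "directed_network"))
  school <- factor(school)
  dummies <- stats::model.matrix(~school)[, -1, drop = FALSE]
  colnames(dummies) <- paste0("school", levels(school)[-1])
  X <- cbind(`(Intercept)` = 1, dummies)
  if (!is.null(X_cov)) X <- cbind(X, as.matrix(X_cov))

  egonet <- build_weight_matrix(classification_from_egonets(net), "equal")
  mm <- fit_mmmc(mmmc_spec(list(egonet = egonet), chain = chain,
                           burnin = burnin, seed = seed), y, X)
  Wrs <- row_standardize(net)
  nd <- fit_nam(y, X, W2 = Wrs, model = "disturbances")

  mm_se <- apply(mm$beta, 2, stats::sd)
  coef_tab <- data.frame(term = colnames(X),
                         est_mm = unname(mm$beta_mean),
                         se_mm = unname(mm_se),
                         est_nd = unname(nd$beta),
                         se_nd = unname(nd$beta_se),
                         row.names = NULL)
  out <- structure(list(coefficients = coef_tab, mm = mm, nd = nd,
                        dic = mm$dic, aic = nd$aic,
                        rho = unname(nd$rho), rho_se = unname(nd$rho_se),
                        egonet_sigma2 = mm$sigma2_mean[["egonet"]],
                        individual_sigma2 = mm$sigma2_mean[["individual"]]),
                   class = "mm_nd_comparison")
  attr(out, "manifest") <- list(seed = seed, chain = chain, burnin = burnin,
                                n = length(y), p = ncol(X))
  out
}

#' @export
print.mm_nd_comparison <- function(x, ...) {
  cat("MM (ego-net + school dummies, MCMC)  vs  network disturbances (ML):\n")
  print(x$coefficients, digits = 3, row.names = FALSE)
  cat(sprintf("MM: ego-net sigma2 = %.3f, individual sigma2 = %.3f, DIC = %.1f\n",
              x$egonet_sigma2, x$individual_sigma2, x$dic))
  cat(sprintf("ND: rho = %.3f (SE %.3f), sigma2 = %.3f, AIC = %.1f\n",
              x$rho, x$rho_se, x$nd$sigma2, x$aic))
  invisible(x)
}
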