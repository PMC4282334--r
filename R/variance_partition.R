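#' Average membership weight factor of a classification
#'
#' A multiple-membership classification contributes
#' \eqn{\sigma^2_k \sum_j w_{ij}^2} to the variance of individual `i`'s
#' response, so its variance component is not directly comparable with the
#' single-membership (school, area) and individual components. Averaging
#' over individuals gives the factor
#' \deqn{f_k = \frac{1}{n} \sum_i \sum_j w_{ij}^2,}
#' which under equal weights reduces to the mean of \eqn{1/n_i} (taking 0
#' for individuals with no memberships): the importance of a network effect
#' is inversely proportional to the number of subgroups an individual
#' belongs to. `f = 1` exactly for single-membership classifications.
#'
#' @param W a `weight_matrix` (or bare matrix) whose rows are the model
#'   weights.
#' @return the scalar factor.
#' @export
average_membership_factor <- function(W) {
  M <- wm_matrix(W)
  sum(M@x^2) / nrow(M)
}

#' Partition response variance across classifications
#'
#' Multiplies each classification's posterior-mean variance component by
#' its average membership weight factor to get the average contribution
#' \eqn{A_k = \sigma^2_k f_k}, and reports the share of each
#' classification (and the individual level) of the factor-adjusted total
#' \eqn{\sigma^2_e + \sum_k A_k}. For a response standardized to unit
#' variance the factor-adjusted total should be close to 1, whereas the
#' raw sum of components typically exceeds 1 for multiple-membership
#' models; both are reported.
#'
#' @param result an `mcmc_result` from [fit_mmmc()].
#' @param factors named numeric vector of average membership factors, one
#'   per classification in the fit (names must match; use 1 for
#'   single-membership classifications, or compute all of them with
#'   [average_membership_factor()]).
#' @return object of class `variance_partition`: a `data.frame` with one
#'   row per classification plus `individual`, columns `sigma2` (posterior
#'   mean), `factor`, `contribution`, `share`; attributes
#'   `adjusted_total` (\eqn{\sigma^2_e + \sum A_k}) and `raw_total`
#'   (\eqn{\sigma^2_e + \sum \sigma^2_k}).
#' @export
variance_shares <- function(result, factors = NULL) {
  stopifnot(inherits(result, "mcmc_result"))
  cls <- setdiff(colnames(result$sigma2), "individual")
  if (is.null(factors)) {
    factors <- vapply(result$spec$classifications[cls], average_membership_factor, 0)
  }
  if (!setequal(names(factors), cls)) {
    stop("factors must be named exactly for the fitted classifications: ",
         paste(cls, collapse = ", "))
  }
  factors <- factors[cls]
  sig2 <- result$sigma2_mean[cls]
  sig2e <- result$sigma2_mean[["individual"]]
  A <- sig2 * factors
  total <- sig2e + sum(A)
  out <- data.frame(
    classification = c(cls, "individual"),
    sigma2 = unname(c(sig2, sig2e)),
    factor = unname(c(factors, 1)),
    contribution = unname(c(A, sig2e)),
    share = unname(c(A, sig2e) / total),
    row.names = NULL
  )
  attr(out, "adjusted_total") <- total
  attr(out, "raw_total") <- sig2e + sum(sig2)
  class(out) <- c("variance_partition", "data.frame")
  out
}

#' @export
print.variance_partition <- function(x, ...) {
  cat("variance partition (average-weight adjusted):\n")
  print.data.frame(x, digits = 3, row.names = FALSE)
  cat(sprintf("adjusted total: %.3f   raw total: %.3f\n",
              attr(x, "adjusted_total"), attr(x, "raw_total")))
  invisible(x)
}
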