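#' Configuration for the synthetic population generator
#'
#' Defaults emulate the structure the analysis assumes for a sampled
#' school-based adolescent friendship study: 968 individuals spread about
#' evenly over 10 schools; 13 areas (counties) nearly nested in schools,
#' with a small fraction of individuals living outside their school's home
#' area; nominations capped at 10 (up to 5 per sex), biased toward
#' same-school and same-sex alters; about 39% sampled-network isolates and
#' a mean ego-net size of about 1.8 among non-isolates; 52% female, 17%
#' black, age about Normal(14.76, 1.5^2) truncated to [10, 19].
#'
#' @param n number of individuals.
#' @param n_schools,n_areas group counts (`n_areas >= n_schools`; areas
#'   beyond the schools' home areas are reached only by crossers).
#' @param crossing_rate probability an individual lives outside their
#'   school's home area.
#' @param nomination_cap maximum nominations per individual (total).
#' @param per_sex_cap maximum nominations per alter sex.
#' @param isolate_target expected fraction of out-degree-zero individuals.
#' @param mean_degree_nonisolate target mean out-degree among non-isolates.
#' @param p_female,p_black covariate prevalences.
#' @param age_mean,age_sd,age_range age distribution (truncated Normal).
#' @param homophily_school,homophily_sex log-odds boost for nominating a
#'   same-school / same-sex alter (0 = uniform choice).
#' @param beta true fixed effects for (intercept, black, female, centred
#'   age), used by the response simulators.
#' @param sigma2 named true variance components (`school`, `area`,
#'   `egonet`, `individual`), at the magnitudes typical of fitted
#'   standardized-attainment models.
#' @param rho true autocorrelation for the network autocorrelation
#'   generators.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n = 968, n_schools = 10, n_areas = 13,
                             crossing_rate = 0.03, nomination_cap = 10,
                             per_sex_cap = 5, isolate_target = 0.39,
                             mean_degree_nonisolate = 1.8,
                             p_female = 0.52, p_black = 0.17,
                             age_mean = 14.76, age_sd = 1.5,
                             age_range = c(10, 19),
                             homophily_school = 3, homophily_sex = 0.7,
                             beta = c(0, -0.05, 0.17, -0.12),
                             sigma2 = c(school = 0.05, area = 0.03,
                                        egonet = 0.15, individual = 0.87),
                             rho = 0.10) {
  stopifnot(n >= 2, n_schools >= 1, n_areas >= n_schools,
            crossing_rate >= 0, crossing_rate <= 1,
            isolate_target >= 0, isolate_target <= 1,
            p_female >= 0, p_female <= 1, p_black >= 0, p_black <= 1,
            nomination_cap >= 0, per_sex_cap >= 0,
            all(sigma2 >= 0), length(beta) == 4)
  if (isolate_target >= 1 && mean_degree_nonisolate > 0) {
    stop("infeasible target: isolate fraction 1 with positive degree")
  }
  structure(as.list(environment()), class = "generator_config")
}

#' Simulate a population: schools, areas, covariates, nomination network
#'
#' Schools get near-equal sizes. Each school has a home area; a configured
#' fraction of individuals cross into another area, so areas are uneven
#' and nearly nested in schools. Out-degrees are drawn from a Poisson
#' calibrated so the non-isolate mean matches the target, thinned to reach
#' the target isolate fraction in expectation (emulating out-of-sample
#' nominations) and capped; alters are then drawn with the configured
#' same-school/same-sex preference.
#'
#' @param cfg a [generator_config()].
#' @param seed RNG seed; the same seed reproduces the dataset exactly.
#' @return object of class `synthetic_population`: `network`
#'   (a [directed_network()]), `covariates` (data.frame with `id`,
#'   `school`, `area`, `female`, `black`, `age`), `config`, `seed`.
#' @export
simulate_population <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(seed)
  n <- cfg$n; S <- cfg$n_schools
  sizes <- rep(n %/% S, S)
  extra <- n - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  school <- sample(rep.int(seq_len(S), sizes))
  area <- school  # home area of school s is area s
  cross <- stats::runif(n) < cfg$crossing_rate
  for (i in which(cross)) {
    area[i] <- sample(setdiff(seq_len(cfg$n_areas), school[i]), 1)
  }
  female <- stats::rbinom(n, 1, cfg$p_female)
  black <- stats::rbinom(n, 1, cfg$p_black)
  age <- rtruncnorm(n, cfg$age_mean, cfg$age_sd, cfg$age_range)

  # out-degrees: truncated-Poisson mean calibrated to the non-isolate target
  m <- integer(n)
  if (cfg$mean_degree_nonisolate > 0 && cfg$isolate_target < 1) {
    lambda <- stats::uniroot(
      function(l) l / (1 - exp(-l)) - cfg$mean_degree_nonisolate,
      c(1e-8, 50))$root
    p0 <- exp(-lambda)
    extra_iso <- max(0, (cfg$isolate_target - p0) / (1 - p0))
    m <- stats::rpois(n, lambda)
    m[m > 0 & stats::runif(n) < extra_iso] <- 0L
    m <- pmin(m, cfg$nomination_cap)
  }

  ii <- integer(0); jj <- integer(0)
  for (i in seq_len(n)) {
    if (m[i] == 0) next
    w <- exp(cfg$homophily_school * (school == school[i]) +
             cfg$homophily_sex * (female == female[i]))
    w[i] <- 0
    alters <- sample.int(n, min(m[i], n - 1), prob = w)
    # per-sex nomination cap
    for (sx in c(0, 1)) {
      of_sex <- alters[female[alters] == sx]
      if (length(of_sex) > cfg$per_sex_cap) {
        alters <- setdiff(alters, of_sex[-seq_len(cfg$per_sex_cap)])
      }
    }
    ii <- c(ii, rep.int(i, length(alters)))
    jj <- c(jj, alters)
  }
  ids <- sprintf("i%04d", seq_len(n))
  D <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  structure(list(
    network = directed_network(D, ids),
    covariates = data.frame(id = ids, school = factor(school),
                            area = factor(area), female = female,
                            black = black, age = age),
    config = cfg, seed = seed
  ), class = "synthetic_population")
}

#' @export
print.synthetic_population <- function(x, ...) {
  cat(sprintf("synthetic_population: n = %d, %d schools, %d areas used\n",
              nrow(x$covariates), nlevels(x$covariates$school),
              length(unique(x$covariates$area))))
  print(x$network)
  invisible(x)
}

# truncated normal by inverse-cdf
rtruncnorm <- function(n, mean, sd, range) {
  lo <- stats::pnorm(range[1], mean, sd)
  hi <- stats::pnorm(range[2], mean, sd)
  stats::qnorm(lo + stats::runif(n) * (hi - lo), mean, sd)
}

#' Fixed-effects design matrix of a synthetic population
#'
#' Intercept, black indicator, female indicator and centred age, the
#' covariate set of the attainment models.
#'
#' @param pop a `synthetic_population`.
#' @return numeric matrix n x 4.
#' @export
design_matrix <- function(pop) {
  stopifnot(inherits(pop, "synthetic_population"))
  cv <- pop$covariates
  cbind(`(Intercept)` = 1, black = cv$black, female = cv$female,
        age_c = cv$age - mean(cv$age))
}

#' Standard classifications of a synthetic population
#'
#' Builds the named weight matrices used throughout: `school` and `area`
#' (single membership), `egonet`, and optionally `clique2`/`clique3` from
#' the symmetrized network.
#'
#' @param pop a `synthetic_population`.
#' @param cliques also enumerate maximal cliques and add the dyad/clique
#'   classifications.
#' @param scheme weighting scheme for the network classifications.
#' @return named list of `weight_matrix` objects.
#' @export
population_classifications <- function(pop, cliques = FALSE, scheme = "equal") {
  stopifnot(inherits(pop, "synthetic_population"))
  ids <- pop$network$node_ids
  out <- list(
    school = build_weight_matrix(
      classification_from_factor(pop$covariates$school, ids, "school"), "equal"),
    area = build_weight_matrix(
      classification_from_factor(pop$covariates$area, ids, "area"), "equal"),
    egonet = build_weight_matrix(classification_from_egonets(pop$network), scheme)
  )
  if (cliques) {
    cs <- enumerate_maximal_cliques(symmetrize(pop$network), min_size = 2)
    maps <- classification_from_cliques(cs, ids, rule = "joint")
    out$clique2 <- build_weight_matrix(maps$clique2, scheme)
    out$clique3 <- build_weight_matrix(maps$clique3, scheme)
  }
  out
}

#' Simulate a response under the MMMC model
#'
#' Draws `y = X beta + sum_k Z_k u_k + e` with independent
#' `u_k ~ N(0, sigma2_k I)` and `e ~ N(0, sigma2_e I)`, then (by default)
#' standardizes to mean 0 and SD 1. The truth record keeps the generating
#' parameters on both the raw and the standardized scale (components
#' divide by the realized variance, coefficients by the realized SD), so
#' recovery checks can compare on the scale actually analysed. The centring
#' is absorbed into the coefficient of the constant design column (if one
#' is present), since that is where an intercept lands after
#' standardization.
#'
#' @param X design matrix.
#' @param classifications named list of `weight_matrix` objects.
#' @param beta,sigma2 generating fixed effects and named variance
#'   components; `sigma2` needs one entry per classification plus
#'   `individual`.
#' @param seed RNG seed.
#' @param standardize standardize the response (default `TRUE`).
#' @return list with `y` and `truth` (`beta`, `sigma2`, `u`, `center`,
#'   `scale`, `beta_scaled`, `sigma2_scaled`, `seed`).
#' @export
simulate_response_mmmc <- function(X, classifications, beta, sigma2, seed = 1,
                                   standardize = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(beta) == ncol(X))
  cls <- names(classifications)
  if (!all(cls %in% names(sigma2)) || !"individual" %in% names(sigma2)) {
    stop("sigma2 must be named for every classification plus 'individual'")
  }
  set.seed(seed)
  y <- drop(X %*% beta)
  u <- list()
  for (k in cls) {
    Z <- wm_matrix(classifications[[k]])
    if (nrow(Z) != n) stop("dimension mismatch for classification '", k, "'")
    u[[k]] <- stats::rnorm(ncol(Z), 0, sqrt(sigma2[[k]]))
    y <- y + as_num(Z %*% u[[k]])
  }
  y <- y + stats::rnorm(n, 0, sqrt(sigma2[["individual"]]))
  center <- 0; scale <- 1
  if (standardize) {
    center <- mean(y)
    scale <- stats::sd(y)
    y <- (y - center) / scale
  }
  sig2_used <- sigma2[c(cls, "individual")]
  # on the standardized scale the centring is absorbed by constant columns
  beta_scaled <- beta / scale
  const_col <- which(apply(X, 2, stats::var) == 0 & X[1, ] != 0)
  if (length(const_col)) {
    beta_scaled[const_col[1]] <- beta_scaled[const_col[1]] -
      center / (scale * X[1, const_col[1]])
  }
  list(y = y,
       truth = list(beta = beta, sigma2 = sig2_used, u = u,
                    center = center, scale = scale,
                    beta_scaled = beta_scaled,
                    sigma2_scaled = sig2_used / scale^2,
                    seed = seed))
}

#' Simulate a response under a network autocorrelation model
#'
#' Effects model: `y = (I - rho W)^{-1} (X beta + eps)`; disturbances
#' model: `y = X beta + (I - rho W)^{-1} eps`; combined:
#' `y = (I - rho1 W1)^{-1} (X beta + (I - rho2 W2)^{-1} eps)`;
#' `eps ~ N(0, sigma2 I)`.
#'
#' @param X design matrix.
#' @param W,W2 weight matrices (`W2` only for `"combined"`, defaults to
#'   `W`).
#' @param rho autocorrelation (length 2 for `"combined"`).
#' @param beta,sigma2 fixed effects and innovation variance.
#' @param model `"effects"`, `"disturbances"` or `"combined"`.
#' @param seed RNG seed.
#' @return numeric response vector with attribute `"truth"`.
#' @export
simulate_response_nam <- function(X, W, rho, beta, sigma2,
                                  model = c("effects", "disturbances", "combined"),
                                  seed = 1, W2 = NULL) {
  model <- match.arg(model)
  X <- as.matrix(X)
  n <- nrow(X)
  W <- wm_matrix(W)
  if (is.null(W2)) W2 <- W else W2 <- wm_matrix(W2)
  rr <- nam_rho(model, rho)
  set.seed(seed)
  eps <- stats::rnorm(n, 0, sqrt(sigma2))
  solve_transform <- function(rho_k, Wk, v) {
    if (rho_k == 0) return(v)
    A <- Matrix::Diagonal(n) - rho_k * Wk
    dt <- Matrix::determinant(A, logarithm = TRUE)
    if (!is.finite(dt$modulus) || dt$sign <= 0) {
      stop("singular transform at rho = ", rho_k)
    }
    as_num(Matrix::solve(A, v))
  }
  if (model == "disturbances") eps <- solve_transform(rr[2], W2, eps)
  y <- drop(X %*% beta) + if (model == "combined")
    solve_transform(rr[2], W2, eps) else eps
  if (model %in% c("effects", "combined")) y <- solve_transform(rr[1], W, y)
  attr(y, "truth") <- list(rho = rho, beta = beta, sigma2 = sigma2,
                           model = model, seed = seed)
  y
}
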