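# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Exhaustive maximal-clique search over all vertex subsets (n <= 12),
# using bit masks. Returns a sorted list of sorted integer vectors.
brute_force_cliques <- function(A, min_size = 2) {
  n <- nrow(A)
  stopifnot(n <= 12)
  masks <- 0:(2^n - 1)
  bit <- bitwShiftL(1L, 0:(n - 1))
  nb <- vapply(seq_len(n), function(v) sum(bit[A[v, ] != 0]), 0)
  complete <- rep(TRUE, length(masks))
  for (v in seq_len(n)) {
    has_v <- bitwAnd(masks, bit[v]) > 0
    rest <- bitwXor(masks, bit[v])     # m minus v where has_v
    complete <- complete & (!has_v | bitwAnd(rest, nb[v]) == rest)
  }
  extendable <- rep(FALSE, length(masks))
  for (w in seq_len(n)) {
    has_w <- bitwAnd(masks, bit[w]) > 0
    extendable <- extendable | (!has_w & bitwAnd(masks, nb[w]) == masks)
  }
  size <- rep(0L, length(masks))
  for (v in seq_len(n)) size <- size + (bitwAnd(masks, bit[v]) > 0)
  sel <- which(complete & !extendable & size >= min_size)
  out <- lapply(masks[sel], function(m) which(bitwAnd(m, bit) > 0))
  key <- vapply(out, function(m) paste(sprintf("%09d", m), collapse = ","), "")
  out[order(key)]
}

# canonical integer-member form of a clique_set for comparison
clique_members_int <- function(cs, node_ids) {
  lapply(cs$cliques, function(m) sort(match(m, node_ids)))
}

# random undirected adjacency matrix (symmetric, zero diagonal)
random_undirected_adj <- function(n, p) {
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  A + t(A)
}

# random directed network object
random_directed_net <- function(n, p, ids = sprintf("n%02d", seq_len(n))) {
  D <- matrix(stats::rbinom(n * n, 1, p), n, n)
  diag(D) <- 0
  netmmmc::directed_network(D, ids)
}

# random multiple-membership structure: K groups, each individual joins
# 0..max_m of them
random_membership_map <- function(n, K, max_m = 4) {
  ids <- sprintf("m%03d", seq_len(n))
  member_index <- lapply(seq_len(n), function(i) {
    m <- sample(0:max_m, 1)
    if (m == 0) integer(0) else sort(sample.int(K, m))
  })
  groups <- rep(list(character(0)), K)
  for (i in seq_len(n)) for (g in member_index[[i]]) {
    groups[[g]] <- c(groups[[g]], ids[i])
  }
  netmmmc::membership_map("rand", groups, ids, member_index = member_index)
}

# dense-algebra Gaussian log-likelihood of the network autocorrelation
# models, written independently of loglik_nam
dense_nam_loglik <- function(model, rho, beta, sigma2, y, X, W1 = NULL, W2 = NULL) {
  n <- length(y)
  I <- diag(n)
  if (model == "effects") { r1 <- rho; r2 <- 0 }
  else if (model == "disturbances") { r1 <- 0; r2 <- rho }
  else { r1 <- rho[1]; r2 <- rho[2] }
  A1 <- if (!is.null(W1)) I - r1 * as.matrix(W1) else I
  A2 <- if (!is.null(W2)) I - r2 * as.matrix(W2) else I
  r <- A2 %*% (A1 %*% y - X %*% beta)
  -n / 2 * log(2 * pi * sigma2) + log(det(A1)) + log(det(A2)) -
    sum(r^2) / (2 * sigma2)
}

# closed-form Gaussian posterior of beta under flat prior with all
# variance components fixed: y ~ N(X beta, V), V = sig2e I + sum sig2k Zk Zk'
conjugate_beta_posterior <- function(y, X, Zs, sig2s, sig2e) {
  n <- length(y)
  V <- diag(sig2e, n)
  for (k in seq_along(Zs)) {
    Zk <- as.matrix(Zs[[k]])
    V <- V + sig2s[k] * tcrossprod(Zk)
  }
  Vi <- solve(V)
  cov <- solve(t(X) %*% Vi %*% X)
  list(mean = drop(cov %*% t(X) %*% Vi %*% y), cov = cov)
}

# small helper: OLS Gaussian log-likelihood at given beta/sigma2
ols_loglik <- function(y, X, beta, sigma2) {
  n <- length(y)
  -n / 2 * log(2 * pi * sigma2) - sum((y - X %*% beta)^2) / (2 * sigma2)
}
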