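#' Membership map: which subgroup effects load on which individuals
#'
#' A classification entering the random part of an MMMC model is described
#' by a membership map: a set of effect columns (one random effect each)
#' together with, for every individual, the set of columns whose effects
#' enter that individual's response. Individuals may load on zero, one or
#' many columns (multiple membership).
#'
#' Two kinds are supported. For subgroup classifications (cliques, schools,
#' areas) the columns are the subgroups and individual `i` loads on every
#' subgroup containing `i`. For the ego-net classification the columns are
#' the individuals themselves (one effect per individual-as-network-member)
#' and `i` loads on the effects of `i`'s alters, so the equal-weight matrix
#' coincides with the row-standardized nomination matrix.
#'
#' @param name classification label.
#' @param groups list of character vectors: the member ids of each subgroup
#'   (for the ego-net kind, each ego's alters).
#' @param node_ids the individual universe (row order of the model).
#' @param member_index optional list, per individual, of column indices that
#'   individual loads on; derived from `groups` by inclusion when `NULL`.
#' @param kind `"subgroup"` or `"egonet"`.
#' @return object of class `membership_map`.
#' @export
membership_map <- function(name, groups, node_ids, member_index = NULL,
                           kind = c("subgroup", "egonet")) {
  kind <- match.arg(kind)
  node_ids <- as.character(node_ids)
  if (anyDuplicated(node_ids)) stop("node ids must be unique")
  groups <- lapply(groups, as.character)
  bad <- !unlist(groups, use.names = FALSE) %in% node_ids
  if (length(bad) && any(bad)) stop("group member(s) outside node universe")
  if (is.null(member_index)) {
    if (kind == "egonet") stop("egonet maps must supply member_index")
    member_index <- rep(list(integer(0)), length(node_ids))
    names(member_index) <- node_ids
    for (g in seq_along(groups)) {
      for (m in groups[[g]]) {
        member_index[[m]] <- c(member_index[[m]], g)
      }
    }
  }
  stopifnot(length(member_index) == length(node_ids))
  names(member_index) <- node_ids
  structure(list(classification = name, groups = groups, node_ids = node_ids,
                 member_index = member_index,
                 n_groups = if (kind == "egonet") length(node_ids) else length(groups),
                 kind = kind),
            class = "membership_map")
}

#' @export
print.membership_map <- function(x, ...) {
  ni <- lengths(x$member_index)
  cat(sprintf("membership_map '%s' (%s): %d columns over %d individuals; %d with no membership\n",
              x$classification, x$kind, x$n_groups, length(x$node_ids), sum(ni == 0)))
  invisible(x)
}

#' Clique classifications from a maximal clique set
#'
#' With `rule = "joint"` the maximal cliques (enumerated at minimum size 2)
#' are split into two classifications used together in one model: the
#' dyad level (maximal cliques of size exactly 2) and the clique level
#' (size at least 3). With `rule = "alone"` all cliques form a single
#' classification. The joint rule partitions the clique set: no clique
#' appears in both classifications.
#'
#' @param cliques a `clique_set` from [enumerate_maximal_cliques()].
#' @param node_ids the individual universe.
#' @param rule `"joint"` or `"alone"`.
#' @return for `"joint"`, a list with `membership_map`s `clique2` and
#'   `clique3`; for `"alone"`, one `membership_map`.
#' @export
classification_from_cliques <- function(cliques, node_ids, rule = c("joint", "alone")) {
  rule <- match.arg(rule)
  stopifnot(inherits(cliques, "clique_set"))
  if (rule == "alone") {
    return(membership_map(sprintf("clique%d", cliques$min_size),
                          cliques$cliques, node_ids))
  }
  sizes <- lengths(cliques$cliques)
  list(
    clique2 = membership_map("clique2", cliques$cliques[sizes == 2], node_ids),
    clique3 = membership_map("clique3", cliques$cliques[sizes >= 3], node_ids)
  )
}

#' Ego-net classification of a directed network
#'
#' One effect per individual-as-network-member; individual `i` loads on the
#' effects of the alters `i` nominates, with `i` excluded from their own
#' ego-net. Isolates load on nothing (zero weight row). The stored
#' `groups[[g]]` is ego `g`'s ego-net (their alters), named `egonet-<id>`;
#' egos with no in-sample alters have an empty entry.
#'
#' @param net a [directed_network()].
#' @return a `membership_map` of kind `"egonet"`.
#' @export
classification_from_egonets <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  n <- length(net$node_ids)
  Dt <- methods::as(Matrix::t(net$D), "CsparseMatrix")   # columns = egos
  member_index <- vector("list", n)
  p <- Dt@p; iidx <- Dt@i
  for (e in seq_len(n)) {
    member_index[[e]] <- sort(iidx[seq.int(p[e] + 1L, length.out = p[e + 1L] - p[e])] + 1L)
  }
  groups <- lapply(member_index, function(ix) net$node_ids[ix])
  names(groups) <- paste0("egonet-", net$node_ids)
  membership_map("egonet", groups, net$node_ids,
                 member_index = member_index, kind = "egonet")
}

#' Single-membership classification from a grouping factor
#'
#' Schools and areas enter the model as single-membership classifications:
#' each individual belongs to exactly one subgroup with weight 1.
#'
#' @param x factor-like vector of group labels, one per individual.
#' @param node_ids the individual universe, same order as `x`.
#' @param name classification label.
#' @return a `membership_map` in which every individual loads on one column.
#' @export
classification_from_factor <- function(x, node_ids, name = deparse(substitute(x))) {
  x <- factor(x)
  node_ids <- as.character(node_ids)
  stopifnot(length(x) == length(node_ids), !anyNA(x))
  groups <- split(node_ids, x)
  names(groups) <- levels(x)
  membership_map(name, groups, node_ids,
                 member_index = as.list(as.integer(x)))
}

#' Build a weight matrix from a membership map
#'
#' The weight matrix `W` (n individuals x K effect columns) carries the
#' weights with which subgroup random effects enter each response. Schemes:
#' `"equal"` gives `1/n_i` to each of individual `i`'s `n_i` memberships so
#' nonzero rows sum to 1 (the scheme used for all main models); `"unit"`
#' gives every membership weight 1 (rows sum to `n_i`); `"inv_sqrt"` gives
#' `1/sqrt(n_i)`. Isolated individuals keep an all-zero row under every
#' scheme. The sparsity pattern is identical across schemes.
#'
#' @param map a `membership_map`.
#' @param scheme `"equal"`, `"unit"` or `"inv_sqrt"`.
#' @return object of class `weight_matrix`: list with `W` (sparse
#'   `dgCMatrix`), `classification`, `scheme` and `kind`
#'   (`"multiple-membership"` or `"single-membership"`).
#' @export
build_weight_matrix <- function(map, scheme = c("equal", "unit", "inv_sqrt")) {
  if (is.character(scheme) && length(scheme) == 1 &&
      !scheme %in% c("equal", "unit", "inv_sqrt")) {
    stop("unknown weighting scheme: ", scheme)
  }
  scheme <- match.arg(scheme)
  stopifnot(inherits(map, "membership_map"))
  n <- length(map$node_ids)
  K <- map$n_groups
  ni <- lengths(map$member_index)
  ii <- rep.int(seq_len(n), ni)
  jj <- unlist(map$member_index, use.names = FALSE)
  xx <- switch(scheme,
    equal    = rep.int(1 / pmax(ni, 1), ni),
    unit     = rep.int(1, sum(ni)),
    inv_sqrt = rep.int(1 / sqrt(pmax(ni, 1)), ni))
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, K))
  rownames(W) <- map$node_ids
  if (map$kind == "egonet") colnames(W) <- map$node_ids
  else if (!is.null(names(map$groups))) colnames(W) <- names(map$groups)
  single <- all(ni == 1)
  structure(list(W = W, classification = map$classification, scheme = scheme,
                 kind = if (single) "single-membership" else "multiple-membership"),
            class = "weight_matrix")
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf("weight_matrix '%s' (%s, scheme %s): %d x %d, %d zero rows\n",
              x$classification, x$kind, x$scheme, nrow(x$W), ncol(x$W),
              sum(Matrix::rowSums(x$W != 0) == 0)))
  invisible(x)
}

#' Extract the numeric matrix from a weight-matrix object
#'
#' @param x a `weight_matrix`, or any matrix (returned as sparse).
#' @return a `dgCMatrix`.
#' @export
wm_matrix <- function(x) {
  if (inherits(x, "weight_matrix")) x <- x$W
  methods::as(methods::as(Matrix::Matrix(x, sparse = TRUE), "generalMatrix"),
              "CsparseMatrix")
}

#' Row-standardized adjacency weight matrix
#'
#' Divides every nonzero row of the nomination matrix `D` by its row sum;
#' isolate rows stay zero. This n x n matrix is the weight matrix of the
#' network autocorrelation models and is elementwise identical to the
#' equal-scheme ego-net weight matrix, so the multiple-membership ego-net
#' model and the network disturbances model use the same weight
#' information.
#'
#' @param net a [directed_network()].
#' @return a `weight_matrix` of kind `"row-standardized-adjacency"`.
#' @export
row_standardize <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  rs <- Matrix::rowSums(net$D)
  W <- Matrix::Diagonal(x = ifelse(rs > 0, 1 / rs, 0)) %*% net$D
  W <- methods::as(W, "CsparseMatrix")
  dimnames(W) <- list(net$node_ids, net$node_ids)
  structure(list(W = W, classification = "egonet", scheme = "equal",
                 kind = "row-standardized-adjacency"),
            class = "weight_matrix")
}
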