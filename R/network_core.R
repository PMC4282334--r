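#' Construct a directed friendship-nomination network
#'
#' A directed network holds the binary nomination matrix `D` in which
#' `D[i, j] = 1` means that individual `i` nominated individual `j` as a
#' friend. Nominations need not be reciprocated, so `D` is in general
#' asymmetric; the diagonal is always zero (self-nominations are removed at
#' parse time).
#'
#' @param D an n x n binary matrix (base or `Matrix` sparse) with zero
#'   diagonal.
#' @param node_ids character vector of unique individual identifiers, in the
#'   row/column order of `D`. Defaults to `rownames(D)`.
#' @return an object of class `directed_network` with elements `node_ids`
#'   and `D` (a sparse `dgCMatrix` with dimnames set to the ids).
#' @seealso [parse_adjacency_list()], [symmetrize()], [ego_alters()]
#' @export
directed_network <- function(D, node_ids = rownames(D)) {
  D <- methods::as(methods::as(Matrix::Matrix(D, sparse = TRUE), "generalMatrix"),
                   "CsparseMatrix")
  if (nrow(D) != ncol(D)) stop("adjacency matrix must be square")
  if (is.null(node_ids)) node_ids <- as.character(seq_len(nrow(D)))
  node_ids <- as.character(node_ids)
  if (anyDuplicated(node_ids)) stop("node ids must be unique")
  if (length(node_ids) != nrow(D)) stop("node_ids length must match matrix dimension")
  vals <- D@x
  if (length(vals) && !all(vals %in% c(0, 1))) stop("adjacency entries must be 0/1")
  if (any(Matrix::diag(D) != 0)) stop("adjacency diagonal must be zero")
  D <- Matrix::drop0(D)
  dimnames(D) <- list(node_ids, node_ids)
  structure(list(node_ids = node_ids, D = D), class = "directed_network")
}

#' @export
print.directed_network <- function(x, ...) {
  cat(sprintf("directed_network: %d nodes, %d nominations, %d isolates\n",
              length(x$node_ids), sum(x$D), sum(Matrix::rowSums(x$D) == 0)))
  invisible(x)
}

#' Parse an adjacency (node) list into a directed network
#'
#' Nomination data typically arrive as an adjacency list: one record per
#' respondent (ego) naming the friends (alters) they nominate. This converts
#' such records into the binary nomination matrix. Self-nominations are set
#' to zero. Nominations of individuals outside the sample universe are, by
#' default, dropped (the nominee is out of sample), which is how sampled
#' networks acquire isolates: an ego all of whose friends are out of sample
#' keeps an all-zero row.
#'
#' @param records a named list: names are ego ids, elements are character
#'   vectors of alter ids (possibly empty). A two-column `data.frame`
#'   (`from`, `to`) edge list is also accepted.
#' @param node_ids optional character vector fixing the sample universe and
#'   node order. Defaults to the egos in order of appearance. Individuals in
#'   `node_ids` never appearing as ego get all-zero rows.
#' @param unknown `"drop"` (default) silently drops alters outside the
#'   universe and records their number in attribute `"n_dropped"`;
#'   `"error"` fails on the first unknown alter.
#' @return a [directed_network()].
#' @examples
#' net <- parse_adjacency_list(list(A = c("B", "C"), B = character(), C = "A"))
#' as.matrix(net$D)
#' @export
parse_adjacency_list <- function(records, node_ids = NULL,
                                 unknown = c("drop", "error")) {
  unknown <- match.arg(unknown)
  if (is.data.frame(records)) {
    if (ncol(records) < 2) stop("edge list must have columns from,to")
    from <- as.character(records[[1]])
    to <- as.character(records[[2]])
    egos <- unique(from)
    records <- lapply(egos, function(e) to[from == e])
    names(records) <- egos
  }
  if (length(records) == 0) stop("empty adjacency list")
  egos <- names(records)
  if (is.null(egos) || any(!nzchar(egos))) stop("records must be named by ego id")
  dup <- egos[duplicated(egos)]
  if (length(dup)) stop("duplicate ego record(s): ", paste(unique(dup), collapse = ", "))
  if (is.null(node_ids)) node_ids <- egos
  node_ids <- as.character(node_ids)
  if (anyDuplicated(node_ids)) stop("node ids must be unique")
  if (!all(egos %in% node_ids)) {
    stop("ego id(s) outside node_ids universe: ",
         paste(setdiff(egos, node_ids), collapse = ", "))
  }
  n <- length(node_ids)
  idx <- stats::setNames(seq_len(n), node_ids)
  ii <- integer(0); jj <- integer(0)
  n_dropped <- 0L
  for (e in egos) {
    alters <- unique(as.character(records[[e]]))
    alters <- setdiff(alters, e)            # self-nominations are zero
    known <- alters %in% node_ids
    if (any(!known)) {
      if (unknown == "error") {
        stop("unknown alter id(s) for ego ", e, ": ",
             paste(alters[!known], collapse = ", "))
      }
      n_dropped <- n_dropped + sum(!known)
      alters <- alters[known]
    }
    if (length(alters)) {
      ii <- c(ii, rep.int(idx[[e]], length(alters)))
      jj <- c(jj, unname(idx[alters]))
    }
  }
  D <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  net <- directed_network(D, node_ids)
  attr(net, "n_dropped") <- n_dropped
  net
}

#' Symmetrize a directed network
#'
#' Produces the undirected adjacency matrix `Dstar` in which `i` and `j` are
#' connected if either nominates the other (or both). `Dstar` is symmetric
#' and at least as dense as `D`; clique analyses are run on it.
#'
#' @param net a [directed_network()].
#' @return an object of class `undirected_network` with elements `node_ids`
#'   and `Dstar`.
#' @export
symmetrize <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  S <- net$D + Matrix::t(net$D)
  S@x[] <- 1
  S <- Matrix::drop0(S)
  dimnames(S) <- list(net$node_ids, net$node_ids)
  structure(list(node_ids = net$node_ids, Dstar = S), class = "undirected_network")
}

#' @export
print.undirected_network <- function(x, ...) {
  cat(sprintf("undirected_network: %d nodes, %d edges\n",
              length(x$node_ids), sum(x$Dstar) / 2))
  invisible(x)
}

#' Ego-net of an individual
#'
#' The ego-net of `i` is the set of individuals `i` nominates (row `i` of
#' the nomination matrix). The ego is never a member of their own ego-net.
#'
#' @param net a [directed_network()].
#' @param i a node id.
#' @return character vector of alter ids (empty for an isolate), in node
#'   order.
#' @export
ego_alters <- function(net, i) {
  stopifnot(inherits(net, "directed_network"))
  pos <- match(as.character(i), net$node_ids)
  if (is.na(pos)) stop("unknown node id: ", i)
  net$node_ids[which(net$D[pos, ] != 0)]
}

#' Enumerate maximal cliques of a minimum size
#'
#' Finds all maximal completely connected subgroups (Luce-Perry cliques) of
#' the undirected network with at least `min_size` members. "Maximal" means
#' no strict superset is also complete, so non-maximal complete subgraphs
#' (e.g. the dyads inside a triangle) are never emitted. Enumeration uses
#' the Bron-Kerbosch algorithm via igraph; output is put in a canonical
#' order (members sorted by node order, cliques lexicographically) so
#' repeated runs are identical.
#'
#' @param unet an `undirected_network` from [symmetrize()].
#' @param min_size minimum clique size, an integer >= 2.
#' @return an object of class `clique_set`: list with `cliques` (list of
#'   character vectors of member ids) and `min_size`.
#' @export
enumerate_maximal_cliques <- function(unet, min_size = 2) {
  stopifnot(inherits(unet, "undirected_network"))
  min_size <- as.integer(min_size)
  if (min_size < 2) stop("min_size must be >= 2")
  n <- length(unet$node_ids)
  g <- igraph::graph_from_adjacency_matrix(unet$Dstar, mode = "undirected")
  raw <- igraph::max_cliques(g, min = min_size)
  cliques <- lapply(raw, function(v) sort(as.integer(v)))
  if (length(cliques)) {
    key <- vapply(cliques, function(m) paste(sprintf("%09d", m), collapse = ","), "")
    cliques <- cliques[order(key)]
  }
  cliques <- lapply(cliques, function(m) unet$node_ids[m])
  structure(list(cliques = cliques, min_size = min_size), class = "clique_set")
}

#' @export
print.clique_set <- function(x, ...) {
  sizes <- lengths(x$cliques)
  cat(sprintf("clique_set: %d maximal cliques of size >= %d", length(sizes), x$min_size))
  if (length(sizes)) cat(sprintf(" (sizes %d..%d)", min(sizes), max(sizes)))
  cat("\n")
  invisible(x)
}

#' Descriptive statistics of a nomination network
#'
#' Summaries used to characterise a sampled friendship network: the number
#' and fraction of isolates (out-degree zero in `D`), the mean ego-net size
#' among non-isolates, and per-individual membership counts for each
#' supplied clique classification.
#'
#' @param net a [directed_network()].
#' @param unet optionally the matching `undirected_network` (only checked
#'   for consistency).
#' @param clique_sets named list of `clique_set` objects.
#' @return object of class `network_summary`: `n`, `n_isolates`,
#'   `isolate_fraction`, `mean_egonet_size_nonisolate`,
#'   `clique_membership_counts` (matrix individuals x classifications),
#'   `max_memberships` (per classification).
#' @export
network_descriptives <- function(net, unet = NULL, clique_sets = list()) {
  stopifnot(inherits(net, "directed_network"))
  if (!is.null(unet) && !identical(unet$node_ids, net$node_ids)) {
    stop("node ids of directed and undirected networks differ")
  }
  outdeg <- Matrix::rowSums(net$D)
  n <- length(net$node_ids)
  n_iso <- sum(outdeg == 0)
  counts <- matrix(0L, nrow = n, ncol = length(clique_sets),
                   dimnames = list(net$node_ids, names(clique_sets)))
  for (k in seq_along(clique_sets)) {
    cs <- clique_sets[[k]]
    stopifnot(inherits(cs, "clique_set"))
    tab <- table(factor(unlist(cs$cliques), levels = net$node_ids))
    counts[, k] <- as.integer(tab)
  }
  structure(list(
    n = n,
    n_isolates = n_iso,
    isolate_fraction = n_iso / n,
    mean_egonet_size_nonisolate = if (n_iso < n) mean(outdeg[outdeg > 0]) else NA_real_,
    clique_membership_counts = counts,
    max_memberships = if (length(clique_sets)) apply(counts, 2, max) else integer(0)
  ), class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("network_summary: n = %d, isolates = %d (%.1f%%)\n",
              x$n, x$n_isolates, 100 * x$isolate_fraction))
  cat(sprintf("  mean ego-net size among non-isolates: %.2f\n",
              x$mean_egonet_size_nonisolate))
  if (ncol(x$clique_membership_counts)) {
    for (nm in colnames(x$clique_membership_counts)) {
      cnt <- x$clique_membership_counts[, nm]
      cat(sprintf("  %s: %.0f%% in no clique, mean memberships %.2f, max %d\n",
                  nm, 100 * mean(cnt == 0), mean(cnt), max(cnt)))
    }
  }
  invisible(x)
}
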