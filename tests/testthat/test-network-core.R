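test_that("adjacency lists parse to the expected nomination matrices", {
  net <- parse_adjacency_list(list(A = c("B", "C"), B = character(), C = character()))
  expect_equal(net$node_ids, c("A", "B", "C"))
  expect_equal(as.matrix(net$D), matrix(c(0, 0, 0, 1, 0, 0, 1, 0, 0), 3,
                                        dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))

  # self-nominations are zeroed
  net2 <- parse_adjacency_list(list(A = c("A", "B"), B = character()))
  expect_equal(net2$D["A", "A"], 0)
  expect_equal(net2$D["A", "B"], 1)

  # out-of-sample alters dropped -> sample isolates
  net3 <- parse_adjacency_list(list(A = "Z", B = "A"))
  expect_equal(unname(Matrix::rowSums(net3$D)["A"]), 0)
  expect_equal(net3$D["B", "A"], 1)
  expect_equal(attr(net3, "n_dropped"), 1L)
  expect_error(parse_adjacency_list(list(A = "Z", B = "A"), unknown = "error"), "Z")

  # universe argument: never-ego individuals get zero rows
  net4 <- parse_adjacency_list(list(A = "B"), node_ids = c("A", "B"))
  expect_equal(unname(Matrix::rowSums(net4$D)), c(1, 0))

  # edge-list input is equivalent
  net5 <- parse_adjacency_list(data.frame(from = c("A", "A"), to = c("B", "C")),
                               node_ids = c("A", "B", "C"))
  expect_equal(as.matrix(net5$D), as.matrix(net$D))
})

test_that("parse errors: duplicate egos and empty input", {
  expect_error(parse_adjacency_list(setNames(list("B", "C"), c("A", "A"))), "A")
  expect_error(parse_adjacency_list(list()), "empty")
  net <- parse_adjacency_list(list(A = "B", B = character()))
  expect_error(ego_alters(net, "Q"), "unknown")
})

test_that("symmetrize takes the elementwise either-direction union", {
  D <- matrix(0, 3, 3); D[1, 2] <- 1
  net <- directed_network(D, c("a", "b", "c"))
  un <- symmetrize(net)
  expect_equal(un$Dstar["a", "b"], 1)
  expect_equal(un$Dstar["b", "a"], 1)
  expect_true(Matrix::isSymmetric(un$Dstar))

  # zero matrix and already-symmetric matrices are fixed points
  z <- directed_network(matrix(0, 4, 4), letters[1:4])
  expect_equal(sum(symmetrize(z)$Dstar), 0)
  S <- matrix(0, 3, 3); S[1, 2] <- S[2, 1] <- 1
  sn <- directed_network(S, c("a", "b", "c"))
  expect_equal(as.matrix(symmetrize(sn)$Dstar), as.matrix(sn$D))
})

test_that("symmetrize is idempotent and monotone under edge addition", {
  set.seed(41)
  for (rep in 1:10) {
    net <- random_directed_net(8, 0.2)
    un <- symmetrize(net)
    un2 <- symmetrize(directed_network(un$Dstar, net$node_ids))
    expect_equal(as.matrix(un2$Dstar), as.matrix(un$Dstar))
    expect_true(sum(un$Dstar) >= sum(net$D))   # density never decreases
    # add one absent edge: Dstar never loses an edge
    off <- which(as.matrix(net$D) == 0 & diag(8) == 0)
    pick <- sample(off, 1)
    D2 <- as.matrix(net$D); D2[pick] <- 1
    un3 <- symmetrize(directed_network(D2, net$node_ids))
    expect_true(all(as.matrix(un3$Dstar) >= as.matrix(un$Dstar)))
  }
})

test_that("ego-nets are the nonzero row entries, ego excluded", {
  D <- matrix(0, 4, 4); D[2, c(1, 3)] <- 1
  net <- directed_network(D, c("w", "x", "y", "z"))
  expect_equal(ego_alters(net, "x"), c("w", "y"))
  expect_equal(ego_alters(net, "w"), character(0))
})

test_that("maximal clique enumeration matches simple cases and is canonical", {
  A <- matrix(0, 3, 3); A[upper.tri(A)] <- 1; A <- A + t(A)
  tri <- directed_network(A, c("1", "2", "3"))
  cs <- enumerate_maximal_cliques(symmetrize(tri), 3)
  expect_equal(cs$cliques, list(c("1", "2", "3")))

  # path 1-2-3-4 has no triangle
  P <- matrix(0, 4, 4)
  P[1, 2] <- P[2, 3] <- P[3, 4] <- 1
  path <- symmetrize(directed_network(P, as.character(1:4)))
  expect_length(enumerate_maximal_cliques(path, 3)$cliques, 0)
  # but three maximal dyads at min_size 2 (non-maximal dyads never emitted)
  expect_length(enumerate_maximal_cliques(path, 2)$cliques, 3)
  expect_error(enumerate_maximal_cliques(path, 1), "min_size")

  # repeated enumeration is byte-identical
  set.seed(7)
  net <- random_directed_net(10, 0.3)
  un <- symmetrize(net)
  expect_identical(enumerate_maximal_cliques(un, 2),
                   enumerate_maximal_cliques(un, 2))
})

test_that("clique enumeration agrees with the exhaustive subset oracle", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(4:12, 1)
    A <- random_undirected_adj(n, stats::runif(1, 0.2, 0.6))
    un <- symmetrize(directed_network(A, sprintf("v%02d", 1:n)))
    for (ms in 2:3) {
      got <- clique_members_int(enumerate_maximal_cliques(un, ms), un$node_ids)
      expect_identical(got, brute_force_cliques(A, ms))
    }
  }
})

test_that("enumeration on a disjoint union equals the union of components", {
  set.seed(55)
  A1 <- random_undirected_adj(6, 0.5)
  A2 <- random_undirected_adj(5, 0.5)
  ids1 <- sprintf("a%d", 1:6); ids2 <- sprintf("b%d", 1:5)
  rec <- c(
    setNames(lapply(1:6, function(i) ids1[A1[i, ] != 0]), ids1),
    setNames(lapply(1:5, function(i) ids2[A2[i, ] != 0]), ids2)
  )
  both <- enumerate_maximal_cliques(symmetrize(parse_adjacency_list(rec)), 2)
  c1 <- enumerate_maximal_cliques(symmetrize(parse_adjacency_list(rec[1:6])), 2)
  c2 <- enumerate_maximal_cliques(symmetrize(parse_adjacency_list(rec[7:11])), 2)
  expect_setequal(lapply(both$cliques, sort),
                  c(lapply(c1$cliques, sort), lapply(c2$cliques, sort)))
})

test_that("network descriptives: isolates, ego-net sizes, clique counts", {
  # star: one ego nominating three alters
  D <- matrix(0, 4, 4); D[1, 2:4] <- 1
  star <- directed_network(D, c("ego", "a", "b", "c"))
  ds <- network_descriptives(star)
  expect_equal(ds$isolate_fraction, 3 / 4)
  expect_equal(ds$mean_egonet_size_nonisolate, 3)

  empty <- directed_network(matrix(0, 5, 5), letters[1:5])
  expect_equal(network_descriptives(empty)$n_isolates, 5)

  # membership counts equal a direct recount
  set.seed(12)
  net <- random_directed_net(15, 0.15)
  un <- symmetrize(net)
  cs <- enumerate_maximal_cliques(un, 2)
  ds2 <- network_descriptives(net, un, list(clique2 = cs))
  recount <- vapply(net$node_ids, function(id)
    sum(vapply(cs$cliques, function(cl) id %in% cl, TRUE)), 0)
  expect_equal(unname(ds2$clique_membership_counts[, "clique2"]), unname(recount))
  expect_equal(unname(ds2$max_memberships[["clique2"]]), max(recount))
})
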