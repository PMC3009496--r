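test_that("bmsi counts at-or-below-threshold correlation partners", {
  # corr(a,b) ~ 0.8 > t, corr(a,c) ~ 0.3 <= t with t = 0.6
  expr <- rbind(a = c(1, 2, 3, 4, 5),
                b = c(1.2, 2.4, 2.6, 4.4, 4.6),
                c = c(3, 1, 4, 1, 5))
  stopifnot(cor(expr["a", ], expr["b", ]) > 0.6, cor(expr["a", ], expr["c", ]) <= 0.6)
  S <- c("a", "b", "c")
  expect_equal(bmsi(S, "a", expr, t = 0.6), 1L)
  expect_error(bmsi(S, "z", expr, t = 0.6), "member")
  # all pairwise correlations above t -> zero for every member
  expr2 <- rbind(a = 1:4, b = c(1, 2, 3, 4.5), c = c(0.9, 2.2, 3, 4))
  for (u in c("a", "b", "c")) expect_equal(bmsi(c("a", "b", "c"), u, expr2, 0.6), 0L)
  # unprofiled members contribute nothing
  expect_equal(bmsi(c("a", "q", "r"), "a", expr, 0.6), 0L)
  expect_equal(bmsi(c("a", "q"), "q", expr, 0.6), 0L)
})

test_that("bmsi matches exhaustive pair enumeration on a random set", {
  set.seed(9)
  expr <- matrix(rnorm(6 * 10), nrow = 6,
                 dimnames = list(letters[1:6], NULL))
  S <- letters[1:6]
  cm <- cor(t(expr))
  for (u in S) {
    manual <- sum(vapply(setdiff(S, u), function(w) cm[u, w] <= 0.2, NA))
    expect_equal(bmsi(S, u, expr, t = 0.2), manual)
  }
})

test_that("clean_neighborhood removes incoherent neighbours and reports components", {
  # star centre v with neighbours a,b,c,d forming a path a-b-c-d
  net <- ppi_network(data.frame(
    from = c("v", "v", "v", "v", "a", "b", "c"),
    to   = c("a", "b", "c", "d", "b", "c", "d"),
    weight = rep(0.9, 7)))
  # no expression: a single 4-vertex component survives untouched
  tn <- clean_neighborhood("v", net)
  expect_equal(tn, list(c("a", "b", "c", "d")))
  # b anticorrelated with everyone else: removed alone, disconnecting a from c-d
  nc <- 10
  set.seed(4)
  base <- rnorm(nc)
  expr <- rbind(a = base + rnorm(nc, sd = .1), b = -base + rnorm(nc, sd = .1),
                c = base + rnorm(nc, sd = .1), d = base + rnorm(nc, sd = .1),
                v = base)
  tn2 <- clean_neighborhood("v", net, expr, t = 0.6)
  expect_equal(tn2, list("a", c("c", "d")))
  # removal can disconnect the surviving neighbourhood into several components
  expect_length(tn2, 2L)
})

test_that("is_q_connected agrees with the exhaustive cut oracle", {
  # two-vertex set joined by one edge: probability is the edge weight
  net <- ppi_network(data.frame(from = "a", to = "b", weight = 0.96))
  expect_true(is_q_connected(c("a", "b"), net, q = 0.95))
  net2 <- ppi_network(data.frame(from = "a", to = "b", weight = 0.94))
  expect_false(is_q_connected(c("a", "b"), net2, q = 0.95))
  # path a-b-c with 0.9 edges: the cut isolating an endpoint has prob 0.9 < 0.95
  path <- ppi_network(data.frame(from = c("a", "b"), to = c("b", "c"),
                                 weight = c(0.9, 0.9)))
  expect_false(is_q_connected(c("a", "b", "c"), path, q = 0.95))
  expect_true(is_q_connected(c("a", "b", "c"), path, q = 0.9))
  # singleton is q-connected; disconnected set is not
  expect_true(is_q_connected("a", path, 0.95))
  expect_false(is_q_connected(c("a", "c"), path, 0.95))
  # weight-1 edges are clamped, not infinite
  sure <- ppi_network(data.frame(from = "a", to = "b", weight = 1))
  expect_true(is_q_connected(c("a", "b"), sure, q = 0.999))

  set.seed(5)
  for (i in 1:50) {
    g <- random_weighted_graph(sample(4:7, 1))
    S <- igraph::V(g)$name
    q <- runif(1, 0.5, 0.99)
    expect_equal(is_q_connected(S, g, q), brute_q_connected(S, g, q),
                 info = paste("graph", i))
  }
})

test_that("q-connectivity is monotone in q and in edge addition", {
  set.seed(6)
  for (i in 1:20) {
    g <- random_weighted_graph(6)
    S <- igraph::V(g)$name
    if (is_q_connected(S, g, 0.9)) {
      expect_true(is_q_connected(S, g, 0.5))
    }
    # adding a strong edge never destroys q-connectivity
    if (is_q_connected(S, g, 0.8)) {
      el <- igraph::as_edgelist(g)
      missing <- utils::combn(S, 2)
      have <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
      cand <- which(!paste(missing[1, ], missing[2, ]) %in% have)
      if (length(cand)) {
        k <- cand[1]
        g2 <- igraph::add_edges(g, c(missing[1, k], missing[2, k]),
                                attr = list(weight = 0.9))
        expect_true(is_q_connected(S, g2, 0.8))
      }
    }
  }
})

test_that("maximal_q_connected splits at weak cuts and keeps the larger side", {
  # already q-connected: identity
  clique <- ppi_network(data.frame(t(utils::combn(letters[1:4], 2)),
                                   weight = 0.99))
  expect_equal(maximal_q_connected(letters[1:4], clique, 0.95), letters[1:4])
  # two dense triangles joined by a weak bridge: larger side is the 0.95 triangle
  # make one side a 4-clique so sizes differ
  net <- ppi_network(rbind(
    data.frame(t(utils::combn(c("a", "b", "c", "d"), 2)), weight = 0.99),
    data.frame(X1 = c("e", "e", "f"), X2 = c("f", "g", "g"), weight = 0.99),
    data.frame(X1 = "d", X2 = "e", weight = 0.5)))
  expect_equal(maximal_q_connected(c("a", "b", "c", "d", "e", "f", "g"), net, 0.95),
               c("a", "b", "c", "d"))
  # all edges weak: no q-connected subset of size >= 2
  weak <- ppi_network(data.frame(from = c("a", "b"), to = c("b", "c"),
                                 weight = c(0.3, 0.3)))
  expect_equal(maximal_q_connected(c("a", "b", "c"), weak, 0.95), character(0))
})

test_that("module_seed composes cleaning and q-connected extraction", {
  # isolated vertex: empty seed
  lone <- ppi_network(data.frame(from = "a", to = "b", weight = 0.9))
  lone <- igraph::add_vertices(lone, 1, name = "z")
  expect_equal(module_seed("z", lone), character(0))
  # hub of a 5-clique with 0.99 weights: the whole clique is the seed
  clique5 <- ppi_network(data.frame(t(utils::combn(letters[1:5], 2)), weight = 0.99))
  expect_equal(module_seed("a", clique5, q = 0.95), letters[1:5])
  # every non-empty seed contains its vertex and induces a connected subgraph
  set.seed(7)
  for (i in 1:10) {
    g <- random_weighted_graph(8, p = 0.4, wmin = 0.5, wmax = 0.99)
    for (v in igraph::V(g)$name) {
      ms <- module_seed(v, g, q = 0.9)
      if (length(ms)) {
        expect_true(v %in% ms)
        expect_gte(length(ms), 3L)
        expect_true(igraph::is_connected(igraph::induced_subgraph(g, ms)))
      }
    }
  }
})
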