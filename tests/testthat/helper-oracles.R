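# Independent brute-force oracles used to check the implementation paths.
# These deliberately use exhaustive enumeration, not the package's own
# algorithms (min cut, phyper, igraph transitivity).

# q-connectivity by enumeration over all 2^(|S|-1) - 1 bipartitions.
brute_q_connected <- function(S, net, q) {
  if (length(S) <= 1L) return(TRUE)
  el <- igraph::as_edgelist(net)
  w <- igraph::E(net)$weight
  keep <- el[, 1L] %in% S & el[, 2L] %in% S
  el <- el[keep, , drop = FALSE]; w <- w[keep]
  n <- length(S)
  anchor <- S[1L]
  rest <- S[-1L]
  for (mask in 0:(2^(n - 1L) - 1L)) {
    U <- c(anchor, rest[bitwAnd(bitwShiftR(mask, seq_len(n - 1L) - 1L), 1L) == 1L])
    comp <- setdiff(S, U)
    if (!length(comp)) next
    crossing <- (el[, 1L] %in% U) != (el[, 2L] %in% U)
    prob <- 1 - prod(1 - w[crossing])
    if (prob < q - 1e-12) return(FALSE)
  }
  TRUE
}

# per-vertex local clustering coefficient by exhaustive triangle counting
brute_clustering_coefficient <- function(g, exclude_deg1 = FALSE) {
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  n <- nrow(adj)
  local <- vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] > 0)
    d <- length(nb)
    if (d < 2L) return(0)
    ev <- sum(adj[nb, nb]) / 2
    2 * ev / (d * (d - 1))
  }, 0)
  if (exclude_deg1) local <- local[igraph::degree(g) >= 2]
  if (!length(local)) 0 else mean(local)
}

# hypergeometric upper tail by direct combinatorial summation
brute_hypergeom_tail <- function(N, M, n, x) {
  is <- x:min(n, M)
  sum(exp(lchoose(M, is) + lchoose(N - M, n - is) - lchoose(N, n)))
}

# random connected-ish weighted graph on n vertices
random_weighted_graph <- function(n, p = 0.5, wmin = 0.3, wmax = 0.99) {
  prs <- utils::combn(paste0("v", seq_len(n)), 2L)
  keep <- stats::runif(ncol(prs)) < p
  if (!any(keep)) keep[sample(ncol(prs), 1L)] <- TRUE
  ppi_network(data.frame(from = prs[1L, keep], to = prs[2L, keep],
                         weight = stats::runif(sum(keep), wmin, wmax)))
}

# tiny 6-vertex / weighted fixture reused in several tests:
# a dense triangle abc (w .95), a dense triangle def (w .9), one weak bridge
toy_two_blob_net <- function(bridge_w = 0.5) {
  ppi_network(data.frame(
    from = c("a", "a", "b", "d", "d", "e", "c"),
    to   = c("b", "c", "c", "e", "f", "f", "d"),
    weight = c(0.95, 0.95, 0.95, 0.9, 0.9, 0.9, bridge_w)))
}

write_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# toy ontology corpus used across the evaluation tests: one aspect chain
# root <- mid <- {leafA, leafB}, plus MF mirror, with hand-chosen annotations
toy_corpus <- function() {
  obo <- c(
    "format-version: 1.2",
    "", "[Term]", "id: GO:1", "name: bp root", "namespace: biological_process",
    "", "[Term]", "id: GO:2", "name: mid", "namespace: biological_process", "is_a: GO:1",
    "", "[Term]", "id: GO:3", "name: leafA", "namespace: biological_process", "is_a: GO:2",
    "", "[Term]", "id: GO:4", "name: leafB", "namespace: biological_process", "is_a: GO:2",
    "", "[Term]", "id: GO:5", "name: mf root", "namespace: molecular_function",
    "", "[Term]", "id: GO:6", "name: mf leaf", "namespace: molecular_function", "is_a: GO:5")
  ann <- c(
    "p1\tGO:3\tBP", "p2\tGO:3\tBP", "p3\tGO:4\tBP", "p4\tGO:4\tBP",
    "p5\tGO:2\tBP", "p6\tGO:1\tBP", "p7\tGO:1\tBP", "p8\tGO:1\tBP",
    "p9\tGO:1\tBP", "p10\tGO:1\tBP",
    "p1\tGO:6\tMF", "p2\tGO:6\tMF", "p3\tGO:5\tMF", "p4\tGO:5\tMF")
  ont <- parse_obo(write_tmp(obo, ".obo"))
  parse_annotations(write_tmp(ann, ".gaf"), ont)
}
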