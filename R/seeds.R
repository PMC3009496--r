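# Capacity used for -log(1 - w) when w == 1: ~ -log of the smallest normal
# double, so any cut containing a weight-1 edge passes every q < 1.
.CAP_MAX <- 745

neglog_capacity <- function(w) {
  cap <- -log1p(-w)
  cap[!is.finite(cap) | cap > .CAP_MAX] <- .CAP_MAX
  cap
}

#' Bad Module Seed Index
#'
#' For a vertex set S in the expression-correlation complete graph and a
#' member u, BMSI(S, u) counts the incident correlation edges of u within S
#' with weight (Pearson correlation) at or below the threshold t.  Pairs in
#' which either protein lacks an expression profile contribute nothing: only
#' profiled-profiled pairs can witness inconsistent expression.
#'
#' @param S character vector of vertex ids.
#' @param u a member of S.
#' @param expr expression matrix (rownames = genes) or NULL.
#' @param t correlation threshold.
#' @return integer count in \[0, |S| - 1\].
#' @export
bmsi <- function(S, u, expr, t) {
  if (!u %in% S) stop("u must be a member of S")
  if (is.null(expr) || !(u %in% rownames(expr))) return(0L)
  others <- setdiff(S, u)
  others <- others[others %in% rownames(expr)]
  if (!length(others)) return(0L)
  pu <- expr[u, ]
  cc <- vapply(others, function(wv) suppressWarnings(pearson_cor(pu, expr[wv, ])), 0)
  sum(cc <= t)
}

#' Clean a vertex neighbourhood by iterative BMSI removal
#'
#' For each connected component NCC of the subgraph induced on N(v), the
#' vertex with the maximum BMSI(NCC, u) is removed and all indices are
#' recomputed, until every remaining BMSI is zero (ties broken by
#' lexicographic vertex id).  The survivors form N'(v); the target
#' neighbourhood TN(v) is the collection of connected components of the
#' subgraph induced on N'(v).  Without expression data no vertex is removed.
#'
#' @param v focal vertex id.
#' @param net weighted igraph network.
#' @param expr expression matrix or NULL.
#' @param t correlation threshold.
#' @return list of character vectors (the TN(v) components), possibly empty.
#' @export
clean_neighborhood <- function(v, net, expr = NULL, t = NA_real_) {
  stopifnot(v %in% igraph::V(net)$name)
  nb <- igraph::V(net)$name[igraph::neighbors(net, v)]
  if (!length(nb)) return(list())
  sub <- igraph::induced_subgraph(net, nb)
  comps <- igraph::components(sub)
  surviving <- character(0)
  for (k in seq_len(comps$no)) {
    ncc <- sort(igraph::V(sub)$name[comps$membership == k])
    if (!is.null(expr) && nrow(expr) > 0L) {
      repeat {
        scores <- vapply(ncc, function(u) bmsi(ncc, u, expr, t), 0L)
        if (!length(scores) || max(scores) == 0L) break
        ncc <- setdiff(ncc, ncc[which.max(scores)])  # ncc sorted: first max is lexicographic
      }
    }
    surviving <- c(surviving, ncc)
  }
  if (!length(surviving)) return(list())
  sub2 <- igraph::induced_subgraph(net, surviving)
  comps2 <- igraph::components(sub2)
  out <- lapply(seq_len(comps2$no), function(k)
    sort(igraph::V(sub2)$name[comps2$membership == k]))
  out[order(vapply(out, `[`, "", 1L))]
}

#' Test whether a vertex set is q-connected
#'
#' A set S is q-connected when, for every bipartition (U, S - U), the
#' probability that at least one crossing interaction truly exists --
#' 1 - prod over crossing edges of (1 - w(e)) -- is at least q.  Decided by a
#' global minimum cut on the subgraph induced on S with edge capacities
#' -log(1 - w), compared against -log(1 - q).  Singletons are q-connected;
#' a disconnected set never is.
#'
#' @param S character vector of vertex ids.
#' @param net weighted igraph network containing S.
#' @param q probability in (0, 1).
#' @return TRUE/FALSE.
#' @export
is_q_connected <- function(S, net, q) {
  stopifnot(q > 0, q < 1, all(S %in% igraph::V(net)$name))
  if (length(S) <= 1L) return(TRUE)
  sub <- igraph::induced_subgraph(net, S)
  if (igraph::components(sub)$no > 1L) return(FALSE)
  cap <- neglog_capacity(igraph::E(sub)$weight)
  cut <- igraph::min_cut(sub, capacity = cap, value.only = TRUE)
  cut >= -log1p(-q) - 1e-9
}

#' Maximal q-connected subset of a connected component
#'
#' If the component is q-connected it is returned whole; otherwise it is
#' split at its global minimum cut and both sides are searched recursively,
#' returning the largest q-connected subset found (maximum cardinality, ties
#' broken by the lexicographically smallest member set).  Singletons are
#' discarded: a q-connected subset of size < 2 yields an empty result.
#'
#' @param S character vector, connected in `net`.
#' @param net weighted igraph network.
#' @param q probability in (0, 1).
#' @return character vector (sorted), possibly empty.
#' @export
maximal_q_connected <- function(S, net, q) {
  if (length(S) < 2L) return(character(0))
  if (is_q_connected(S, net, q)) return(sort(S))
  sub <- igraph::induced_subgraph(net, S)
  comps <- igraph::components(sub)
  if (comps$no > 1L) {
    parts <- lapply(seq_len(comps$no), function(k)
      igraph::V(sub)$name[comps$membership == k])
  } else {
    cap <- neglog_capacity(igraph::E(sub)$weight)
    cut <- igraph::min_cut(sub, capacity = cap, value.only = FALSE)
    parts <- list(igraph::V(sub)$name[as.integer(cut$partition1)],
                  igraph::V(sub)$name[as.integer(cut$partition2)])
  }
  best <- character(0)
  for (p in parts) {
    cand <- maximal_q_connected(p, net, q)
    if (length(cand) > length(best) ||
        (length(cand) == length(best) && length(cand) &&
         paste(cand, collapse = ",") < paste(best, collapse = ","))) {
      best <- cand
    }
  }
  best
}

#' Module seed of a vertex
#'
#' Composes neighbourhood cleaning and maximal q-connected extraction:
#' MQC(v) is the largest maximal q-connected subset over the TN(v)
#' components (ties to the lexicographically smallest set); the seed MS(v)
#' is MQC(v) plus v itself when |MQC(v)| > 1, otherwise empty.
#'
#' @param v vertex id.
#' @param net weighted igraph network.
#' @param expr expression matrix or NULL.
#' @param t correlation threshold (ignored when `expr` is NULL).
#' @param q q-connectivity threshold, default 0.95 (error probability 0.05).
#' @return character vector: seed members including v, or empty.
#' @export
module_seed <- function(v, net, expr = NULL, t = NA_real_, q = 0.95) {
  tn <- clean_neighborhood(v, net, expr, t)
  mqc <- character(0)
  for (comp in tn) {
    cand <- maximal_q_connected(comp, net, q)
    if (length(cand) > length(mqc) ||
        (length(cand) == length(mqc) && length(cand) &&
         paste(cand, collapse = ",") < paste(mqc, collapse = ","))) {
      mqc <- cand
    }
  }
  if (length(mqc) > 1L) sort(c(mqc, v)) else character(0)
}

#' Module seeds for every vertex
#'
#' @inheritParams module_seed
#' @param verbose print progress every 500 vertices.
#' @return named list vertex -> seed member vector (possibly empty).
#' @export
module_seeds <- function(net, expr = NULL, t = NA_real_, q = 0.95, verbose = FALSE) {
  vs <- igraph::V(net)$name
  out <- vector("list", length(vs))
  names(out) <- vs
  for (i in seq_along(vs)) {
    out[[i]] <- module_seed(vs[i], net, expr, t, q)
    if (verbose && i %% 500L == 0L) message("seeds: ", i, "/", length(vs))
  }
  out
}
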