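#' Pearson correlation between two expression profiles
#'
#' Standard sample Pearson correlation.  A zero-variance profile makes the
#' correlation undefined; it is treated as 0 (so the pair can never pass a
#' positive correlation threshold) with a warning.
#'
#' @param x,y equal-length numeric vectors (length >= 3).
#' @return correlation in \[-1, 1\].
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance expression profile; correlation set to 0")
    return(0)
  }
  stats::cor(x, y)
}

# Pairwise correlation matrix over the rows of an expression matrix.
# Zero-variance rows get correlation 0 against everything.
correlation_matrix <- function(expr) {
  sds <- apply(expr, 1L, stats::sd)
  cm <- suppressWarnings(stats::cor(t(expr)))
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance profile(s); correlations set to 0")
    cm[sds == 0, ] <- 0
    cm[, sds == 0] <- 0
  }
  diag(cm) <- 1
  cm
}

#' Clustering coefficient of a graph
#'
#' Mean over all vertices of the local clustering coefficient
#' 2 E_v / (deg(v) (deg(v) - 1)), where E_v is the number of edges among v's
#' neighbours.  Vertices of degree < 2 contribute 0 and are included in the
#' mean (Watts-Strogatz convention); set `exclude_deg1 = TRUE` to average
#' over degree >= 2 vertices only.
#'
#' @param h simple undirected igraph graph.
#' @param exclude_deg1 drop degree < 2 vertices from the mean instead.
#' @return scalar in \[0, 1\].
#' @export
clustering_coefficient <- function(h, exclude_deg1 = FALSE) {
  if (igraph::vcount(h) == 0L) stop("empty graph")
  local <- igraph::transitivity(h, type = "local", isolates = "zero")
  if (exclude_deg1) {
    keep <- igraph::degree(h) >= 2
    if (!any(keep)) return(0)
    local <- local[keep]
  }
  mean(local)
}

#' Degree-preserving random rewiring
#'
#' Produces a random graph with the identical degree sequence by repeated
#' double-edge swaps that reject self-loops and multi-edges.  Deterministic
#' given `seed`.
#'
#' @param h simple undirected igraph graph.
#' @param n_swaps number of attempted swaps; default 10 |E|.
#' @param seed optional integer seed (RNG state is restored on exit).
#' @return rewired graph with the same degree sequence.
#' @export
degree_preserving_null <- function(h, n_swaps = 10L * igraph::ecount(h), seed = NULL) {
  if (igraph::ecount(h) < 2L) {
    warning("fewer than 2 edges; returning graph unchanged")
    return(h)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  igraph::rewire(h, igraph::keeping_degseq(niter = n_swaps))
}

#' Select the correlation threshold from expression data
#'
#' Builds the complete correlation graph K_r over the `r` profiled genes and,
#' for each candidate cutoff d_j = 0.6 + 0.01 j (j = 0..39), compares the
#' clustering coefficient C(K_r, d_j) of the subgraph H (edges with
#' correlation > d_j) against C_0(K_r, d_j), its mean over `n_null`
#' degree-preserving random rewirings.  The threshold t is the grid point
#' maximizing C - C_0, ties broken toward the smaller cutoff.  A structured
#' correlation graph is more clustered than its degree-matched null, so the
#' gap peaks where genuine co-expression structure is best separated from
#' background.
#'
#' @param expr numeric expression matrix (genes x conditions, rownames).
#' @param n_null number of null rewirings averaged per grid point.
#' @param seed integer seed driving the null rewirings.
#' @param grid_start,grid_step,grid_n candidate-cutoff grid parameters.
#' @return object of class `threshold_scan`: data.frame `scan` with columns
#'   `d`, `C`, `C0`, `gap`, and the chosen threshold `t`.
#' @export
select_threshold <- function(expr, n_null = 5L, seed = 1L,
                             grid_start = 0.6, grid_step = 0.01, grid_n = 40L) {
  stopifnot(nrow(expr) >= 3L)
  grid <- grid_start + grid_step * (seq_len(grid_n) - 1L)
  cm <- correlation_matrix(expr)
  r <- nrow(cm)
  ut <- upper.tri(cm)
  idx <- which(ut, arr.ind = TRUE)
  cvals <- cm[ut]
  scan <- data.frame(d = grid, C = NA_real_, C0 = NA_real_, gap = NA_real_)
  any_edges <- FALSE
  for (j in seq_along(grid)) {
    keep <- cvals > grid[j]
    if (!any(keep)) {
      scan$C[j] <- 0; scan$C0[j] <- 0; scan$gap[j] <- 0
      next
    }
    any_edges <- TRUE
    h <- igraph::graph_from_edgelist(
      cbind(rownames(cm)[idx[keep, 1L]], rownames(cm)[idx[keep, 2L]]),
      directed = FALSE)
    h <- h + igraph::vertices(setdiff(rownames(cm), igraph::V(h)$name))
    scan$C[j] <- clustering_coefficient(h)
    nulls <- vapply(seq_len(n_null), function(k) {
      h0 <- suppressWarnings(
        degree_preserving_null(h, seed = seed + 1000L * j + k))
      clustering_coefficient(h0)
    }, 0)
    scan$C0[j] <- mean(nulls)
    scan$gap[j] <- scan$C[j] - scan$C0[j]
  }
  if (!any_edges) stop("no correlated pairs above ", grid_start)
  t <- grid[which.max(scan$gap)]  # which.max returns first (smallest d) on ties
  structure(list(scan = scan, t = t, r = r), class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat("correlation threshold scan over", nrow(x$scan), "cutoffs,", x$r, "genes\n")
  cat("chosen t =", x$t, "(max C - C0 =", max(x$scan$gap), ")\n")
  invisible(x)
}

#' Filter PPI edges by expression consistency
#'
#' Removes edge (a, b) iff both endpoints have expression profiles and their
#' Pearson correlation is <= t (the same at-or-below-threshold convention as
#' the bad-module-seed index).  Edges with at least one unprofiled endpoint
#' are retained; the vertex set is unchanged, so filtering may leave isolated
#' vertices.  With no expression data the network is returned unchanged.
#'
#' @param net weighted igraph network.
#' @param expr expression matrix or NULL.
#' @param t correlation threshold in \[-1, 1\].
#' @return filtered network.
#' @export
filter_network <- function(net, expr, t) {
  if (is.null(expr) || nrow(expr) == 0L) return(net)
  stopifnot(t >= -1, t <= 1)
  el <- igraph::as_edgelist(net)
  profiled <- rownames(expr)
  both <- el[, 1L] %in% profiled & el[, 2L] %in% profiled
  if (!any(both)) return(net)
  sub <- expr[unique(c(el[both, 1L], el[both, 2L])), , drop = FALSE]
  cm <- correlation_matrix(sub)
  cc <- cm[cbind(el[both, 1L], el[both, 2L])]
  drop <- which(both)[cc <= t]
  if (length(drop)) net <- igraph::delete_edges(net, drop)
  net
}
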