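#' Grow a module seed by the neighbourhood-majority join rule
#'
#' In each iteration every vertex u adjacent to the current module M with
#' 2 |N(u) ∩ M| > |M| is identified, and all qualifying vertices are joined
#' simultaneously (batch semantics: the bar is the size of M before any of
#' them joins).  Iterates until no vertex qualifies.  Growth is monotone and
#' terminates in at most |V| iterations.
#'
#' @param seed character vector of seed members (non-empty).
#' @param net igraph network.
#' @return sorted character vector of grown-module members.
#' @export
grow_module <- function(seed, net) {
  if (!length(seed)) stop("empty seed cannot be grown")
  members <- sort(unique(seed))
  repeat {
    frontier <- setdiff(
      unique(unlist(igraph::adjacent_vertices(net, members), use.names = FALSE)),
      match(members, igraph::V(net)$name))
    if (!length(frontier)) break
    cand <- igraph::V(net)$name[frontier]
    joins <- vapply(cand, function(u) {
      nb <- igraph::V(net)$name[igraph::neighbors(net, u)]
      2L * length(intersect(nb, members)) > length(members)
    }, NA)
    if (!any(joins)) break
    members <- sort(c(members, cand[joins]))
  }
  members
}

#' Radicchi weak-community test
#'
#' A vertex set is a weak community when the sum of its members' internal
#' degrees exceeds the sum of their external degrees (equivalently
#' 2 E_in > E_out), evaluated on the unweighted topology by default.  With
#' `weighted = TRUE` edge weights replace edge counts.  The full vertex set
#' is a weak community by convention (no external edges).
#'
#' @param module character vector of vertex ids.
#' @param net igraph network.
#' @param weighted use confidence scores instead of edge counts.
#' @return TRUE/FALSE.
#' @export
is_weak_community <- function(module, net, weighted = FALSE) {
  stopifnot(length(module) > 0L, all(module %in% igraph::V(net)$name))
  if (length(module) == igraph::vcount(net)) {
    warning("module is the whole vertex set; weak by convention")
    return(TRUE)
  }
  el <- igraph::as_edgelist(net)
  w <- if (weighted) igraph::E(net)$weight else rep(1, nrow(el))
  in1 <- el[, 1L] %in% module
  in2 <- el[, 2L] %in% module
  e_in <- sum(w[in1 & in2])
  e_out <- sum(w[xor(in1, in2)])
  2 * e_in > e_out
}

#' Merge overlapping grown modules into the final clustering
#'
#' Two modules merge when twice their overlap exceeds the size of the
#' smaller one.  Identical member sets are collapsed first; then the
#' mergeable pair with the largest overlap ratio |U_i ∩ U_j| / min(|U_i|,
#' |U_j|) is merged (ties: lexicographically smallest index pair), repeating
#' until no pair qualifies.  The result is ordered by decreasing size, then
#' lexicographically, and at the fixpoint no two modules satisfy the merge
#' criterion.
#'
#' @param grown list of character vectors (possibly with duplicates).
#' @param seed_vertex optional character vector of provenance seed vertices,
#'   parallel to `grown`.
#' @return `hunter_clustering` with a merge log in `$log`.
#' @export
merge_modules <- function(grown, seed_vertex = NULL) {
  grown <- lapply(grown, function(m) sort(unique(m)))
  if (is.null(seed_vertex)) seed_vertex <- rep("-", length(grown))
  keys <- vapply(grown, paste, "", collapse = ",")
  keep <- !duplicated(keys)
  mods <- grown[keep]
  seeds <- vapply(split(seed_vertex, factor(keys, levels = keys[keep])),
                  function(s) paste(unique(s), collapse = "|"), "")
  merges <- character(0)
  repeat {
    n <- length(mods)
    if (n < 2L) break
    best <- NULL; best_ratio <- -1
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        ov <- length(intersect(mods[[i]], mods[[j]]))
        mn <- min(length(mods[[i]]), length(mods[[j]]))
        if (2L * ov > mn) {
          ratio <- ov / mn
          if (ratio > best_ratio) { best_ratio <- ratio; best <- c(i, j) }
        }
      }
    }
    if (is.null(best)) break
    i <- best[1L]; j <- best[2L]
    merges <- c(merges, sprintf("%d+%d(ratio %.3f)", i, j, best_ratio))
    mods[[i]] <- sort(union(mods[[i]], mods[[j]]))
    seeds[i] <- paste(unique(c(strsplit(seeds[i], "|", fixed = TRUE)[[1L]],
                               strsplit(seeds[j], "|", fixed = TRUE)[[1L]])), collapse = "|")
    mods <- mods[-j]; seeds <- seeds[-j]
    # a merge can create a duplicate of an existing set
    keys <- vapply(mods, paste, "", collapse = ",")
    keep <- !duplicated(keys)
    mods <- mods[keep]; seeds <- seeds[keep]
  }
  ord <- order(-lengths(mods), vapply(mods, paste, "", collapse = ","))
  mods <- mods[ord]; seeds <- seeds[ord]
  names(mods) <- sprintf("module_%d", seq_along(mods))
  new_clustering(mods, seed_vertex = unname(seeds), log = list(merges = merges))
}

#' Run the full module-detection pipeline
#'
#' Stages: (1) if expression data is supplied, select the correlation
#' threshold (unless `t` is given) and strip inconsistently expressed PPI
#' edges; (2) build a module seed for every vertex of the target network;
#' (3) grow each non-empty seed by the majority join rule; (4) keep grown
#' modules that are weak communities; (5) collapse duplicates and merge
#' overlapping modules; (6) report final modules of at least `min_size`
#' members.
#'
#' @param net weighted igraph network.
#' @param expr expression matrix or NULL.
#' @param q q-connectivity threshold, default 0.95.
#' @param t correlation threshold, or `"auto"` to select it from `expr`.
#' @param min_size minimum reported module size (default 3).
#' @param seed integer RNG seed for threshold-selection nulls.
#' @param n_null null replicates per grid point in threshold selection.
#' @param verbose log per-stage counts via message().
#' @return `hunter_clustering`; `$log` records the chosen threshold and
#'   per-stage counts.
#' @export
run_pipeline <- function(net, expr = NULL, q = 0.95, t = "auto", min_size = 3L,
                         seed = 1L, n_null = 5L, verbose = FALSE) {
  log <- list()
  tval <- NA_real_
  if (!is.null(expr) && nrow(expr) > 0L) {
    expr <- expr[rownames(expr) %in% igraph::V(net)$name, , drop = FALSE]
    log$n_profiled <- nrow(expr)
    if (nrow(expr) == 0L) {
      expr <- NULL
    } else {
      tval <- if (identical(t, "auto")) select_threshold(expr, n_null = n_null, seed = seed)$t
              else as.numeric(t)
      log$t <- tval
      net_before <- igraph::ecount(net)
      net <- filter_network(net, expr, tval)
      log$edges_removed <- net_before - igraph::ecount(net)
      if (verbose) message("threshold t = ", tval, "; removed ",
                           log$edges_removed, " edges")
    }
  }
  seeds <- module_seeds(net, expr, tval, q, verbose = verbose)
  seeds <- seeds[lengths(seeds) > 0L]
  log$n_seeds <- length(seeds)
  if (verbose) message(length(seeds), " non-empty seeds")
  if (!length(seeds)) {
    cl <- new_clustering(list(), log = log)
    return(cl)
  }
  grown <- lapply(seeds, grow_module, net = net)
  weak <- vapply(grown, is_weak_community, NA, net = net)
  log$n_grown_weak <- sum(weak)
  if (verbose) message(sum(weak), " grown modules pass the weak-community test")
  grown <- grown[weak]
  if (!length(grown)) return(new_clustering(list(), log = log))
  cl <- merge_modules(grown, seed_vertex = names(grown))
  keep <- lengths(cl$modules) >= min_size
  cl$modules <- cl$modules[keep]
  cl$seed_vertex <- cl$seed_vertex[keep]
  names(cl$modules) <- sprintf("module_%d", seq_along(cl$modules))
  log$n_final <- length(cl$modules)
  cl$log <- c(cl$log, log)
  if (verbose) message(length(cl$modules), " final modules")
  cl
}
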