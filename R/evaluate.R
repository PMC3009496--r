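ASPECT_CODES <- c(P = "BP", F = "MF", C = "CC")

#' Parse an OBO 1.2 ontology file
#'
#' Reads `[Term]` stanzas with `id`, `name`, `namespace`, `is_a` and
#' `relationship: part_of` fields.  Both is_a and part_of count as parent
#' links (a term inherits all the relationships of its parents).  Obsolete
#' terms are skipped with a warning.  Cyclic parent structure is an error.
#'
#' @param path OBO file path.
#' @return object of class `go_ontology`: per-term parents, namespaces and a
#'   precomputed ancestor closure (each term is its own ancestor).
#' @export
parse_obo <- function(path) {
  lines <- readLines(path)
  ids <- character(0); names_ <- character(0); ns <- character(0)
  parents <- list()
  cur <- NULL
  flush <- function() {
    if (is.null(cur) || is.null(cur$id)) return()
    if (isTRUE(cur$obsolete)) {
      warning("skipping obsolete term ", cur$id)
      return()
    }
    ids <<- c(ids, cur$id)
    names_ <<- c(names_, if (is.null(cur$name)) cur$id else cur$name)
    ns <<- c(ns, if (is.null(cur$ns)) NA_character_ else cur$ns)
    parents[[cur$id]] <<- unique(cur$parents)
  }
  in_term <- FALSE
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)  # trailing comments
    ln <- trimws(ln)
    if (ln == "[Term]") { flush(); cur <- list(parents = character(0)); in_term <- TRUE; next }
    if (grepl("^\\[", ln)) { flush(); cur <- NULL; in_term <- FALSE; next }
    if (!in_term || !nzchar(ln)) next
    if (startsWith(ln, "id:")) cur$id <- trimws(sub("^id:", "", ln))
    else if (startsWith(ln, "name:")) cur$name <- trimws(sub("^name:", "", ln))
    else if (startsWith(ln, "namespace:")) cur$ns <- trimws(sub("^namespace:", "", ln))
    else if (startsWith(ln, "is_a:")) cur$parents <- c(cur$parents, trimws(sub("^is_a:", "", ln)))
    else if (startsWith(ln, "relationship:")) {
      rel <- strsplit(trimws(sub("^relationship:", "", ln)), "[ \t]+")[[1L]]
      if (length(rel) >= 2L && rel[1L] == "part_of") cur$parents <- c(cur$parents, rel[2L])
    }
    else if (startsWith(ln, "is_obsolete:")) {
      cur$obsolete <- grepl("true", ln, fixed = TRUE)
    }
  }
  flush()
  names(ns) <- ids; names(names_) <- ids
  parents <- lapply(parents, function(p) p[p %in% ids])
  # ancestor closure with cycle detection (DFS, grey/black marking)
  anc <- new.env(parent = emptyenv())
  state <- new.env(parent = emptyenv())
  visit <- function(id) {
    st <- mget(id, state, ifnotfound = "white")[[1L]]
    if (st == "grey") stop("cyclic is_a/part_of structure at ", id)
    if (st == "black") return(get(id, anc))
    assign(id, "grey", state)
    a <- id
    for (p in parents[[id]]) a <- union(a, visit(p))
    assign(id, a, anc)
    assign(id, "black", state)
    a
  }
  for (id in ids) visit(id)
  ancestors <- mget(ids, anc)
  # map long namespace names to aspect codes
  aspect <- c(biological_process = "BP", molecular_function = "MF",
              cellular_component = "CC")[ns]
  names(aspect) <- ids
  structure(list(ids = ids, name = names_, aspect = aspect,
                 parents = parents, ancestors = ancestors),
            class = "go_ontology")
}

#' Parse annotations and build an annotation corpus
#'
#' Accepts GAF-like tab-delimited records (comment lines start with `!`;
#' protein id in column 2, qualifier in column 4, GO id in column 5, aspect
#' letter P/F/C in column 9; `NOT` qualifiers are skipped) or a minimal
#' three-column `protein<TAB>go_id<TAB>aspect` format.  Annotations are
#' propagated upward through the DAG, and per-aspect term probabilities
#' p(a) = (proteins annotated to a) / (proteins annotated to any term in the
#' aspect DAG) are computed from the propagated sets.
#'
#' @param path annotation file path.
#' @param ontology a `go_ontology` from [parse_obo()].
#' @return object of class `annotation_corpus`: per-aspect direct and
#'   propagated protein->term maps, term->protein maps and term
#'   probabilities.
#' @export
parse_annotations <- function(path, ontology) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (!length(lines)) stop("empty annotation file: ", path)
  parts <- strsplit(lines, "\t")
  rec <- lapply(parts, function(p) {
    if (length(p) >= 9L) {
      if (grepl("NOT", p[4L], fixed = TRUE)) return(NULL)
      c(p[2L], p[5L], unname(ASPECT_CODES[p[9L]]))
    } else if (length(p) == 3L) {
      asp <- if (p[3L] %in% names(ASPECT_CODES)) unname(ASPECT_CODES[p[3L]]) else p[3L]
      c(p[1L], p[2L], asp)
    } else {
      stop("malformed annotation line: ", paste(p, collapse = " "))
    }
  })
  rec <- do.call(rbind, rec[!vapply(rec, is.null, NA)])
  known <- rec[, 2L] %in% ontology$ids
  if (!all(known)) {
    warning(sum(!known), " annotation(s) to unknown term(s) skipped")
    rec <- rec[known, , drop = FALSE]
  }
  build_corpus(rec[, 1L], rec[, 2L], rec[, 3L], ontology)
}

build_corpus <- function(protein, term, aspect, ontology) {
  aspects <- list()
  for (asp in c("BP", "MF", "CC")) {
    sel <- aspect == asp & ontology$aspect[term] == asp
    if (!any(sel)) next
    direct <- lapply(split(term[sel], protein[sel]), unique)
    prop <- lapply(direct, function(ts)
      unique(unlist(ontology$ancestors[ts], use.names = FALSE)))
    term_proteins <- lapply(
      split(rep(names(prop), lengths(prop)), unlist(prop, use.names = FALSE)),
      unique)
    n_ann <- length(prop)
    p <- vapply(term_proteins, length, 0L) / n_ann
    aspects[[asp]] <- list(direct = direct, propagated = prop,
                           term_proteins = term_proteins, p = p,
                           n_annotated = n_ann)
  }
  if (!length(aspects)) stop("no usable annotations")
  structure(list(ontology = ontology, aspects = aspects),
            class = "annotation_corpus")
}

#' @export
print.annotation_corpus <- function(x, ...) {
  cat("annotation corpus:", length(x$ontology$ids), "terms\n")
  for (asp in names(x$aspects)) {
    cat(" ", asp, ":", x$aspects[[asp]]$n_annotated, "annotated proteins,",
        length(x$aspects[[asp]]$p), "used terms\n")
  }
  invisible(x)
}

#' Hypergeometric enrichment p-value
#'
#' Upper-tail probability of observing `x` or more annotated proteins in a
#' cluster of size `n` drawn from a background of `N` proteins of which `M`
#' carry the term.
#'
#' @param N background size; @param M term-annotated proteins in background;
#' @param n cluster size; @param x term-annotated proteins in the cluster.
#' @return p-value in \[0, 1\].
#' @export
enrichment_pvalue <- function(N, M, n, x) {
  if (M > N || n > N || x > min(n, M) || any(c(N, M, n, x) < 0)) {
    stop(sprintf("inconsistent counts N=%d M=%d n=%d x=%d", N, M, n, x))
  }
  if (x == 0L) return(1)
  stats::phyper(x - 1L, M, N - M, n, lower.tail = FALSE)
}

#' GO-term retrieval F-measure of a clustering
#'
#' Sensitivity: fraction of the aspect's annotations (terms annotating at
#' least one but not every background protein; universal terms such as the
#' root can never be enriched) that are enriched in at least one cluster at
#' p < alpha.  Specificity: fraction of clusters enriched for at least one
#' such term.  F is their harmonic mean (0 when both are 0).
#'
#' @param clustering `hunter_clustering` or list of character vectors.
#' @param corpus `annotation_corpus`.
#' @param aspect "BP", "MF" or "CC".
#' @param alpha raw p-value cutoff, default 1e-4 (no multiple-testing
#'   correction; set `bonferroni = TRUE` to divide alpha by the number of
#'   tested terms per cluster).
#' @param background protein universe; default: all proteins annotated in
#'   the aspect.
#' @param bonferroni apply a Bonferroni-adjusted cutoff.
#' @return list: sensitivity, specificity, f, and per-cluster enriched terms
#'   with p-values.
#' @export
f_measure <- function(clustering, corpus, aspect = "BP", alpha = 1e-4,
                      background = NULL, bonferroni = FALSE) {
  mods <- if (inherits(clustering, "hunter_clustering")) clustering$modules else clustering
  if (!length(mods)) stop("empty clustering")
  a <- corpus$aspects[[aspect]]
  if (is.null(a)) stop("no annotations for aspect ", aspect)
  if (is.null(background)) background <- names(a$propagated)
  annotated_bg <- intersect(background, names(a$propagated))
  N <- length(annotated_bg)
  tp <- lapply(a$term_proteins, intersect, annotated_bg)
  M <- vapply(tp, length, 0L)
  terms <- names(tp)[M >= 1L & M < N]
  if (!length(terms)) stop("no informative terms in aspect ", aspect)
  cutoff <- if (bonferroni) alpha / length(terms) else alpha
  enriched_terms <- character(0)
  per_cluster <- vector("list", length(mods))
  names(per_cluster) <- names(mods)
  cluster_hit <- logical(length(mods))
  for (i in seq_along(mods)) {
    cl <- intersect(mods[[i]], annotated_bg)
    n <- length(cl)
    hits <- list()
    if (n > 0L) {
      for (tm in terms) {
        x <- length(intersect(cl, tp[[tm]]))
        if (x == 0L) next
        p <- enrichment_pvalue(N, M[[tm]], n, x)
        if (p < cutoff) hits[[tm]] <- p
      }
    }
    per_cluster[[i]] <- unlist(hits)
    if (length(hits)) {
      cluster_hit[i] <- TRUE
      enriched_terms <- union(enriched_terms, names(hits))
    }
  }
  sens <- length(enriched_terms) / length(terms)
  spec <- mean(cluster_hit)
  f <- if (sens + spec == 0) 0 else 2 * sens * spec / (sens + spec)
  list(sensitivity = sens, specificity = spec, f = f, enriched = per_cluster)
}

#' Schlicker relevance similarity of two GO terms
#'
#' max over common ancestors c of
#' \[2 ln p(c) / (ln p(a1) + ln p(a2))\] (1 - p(c)).  The (1 - p) factor
#' zeroes uninformative shallow ancestors (the root has p = 1); a pair whose
#' only common ancestor is the root scores 0.  Symmetric, and
#' sim(a, a) = 1 - p(a).
#'
#' @param a1,a2 term ids present in the aspect DAG.
#' @param corpus `annotation_corpus`.
#' @param aspect ontology aspect.
#' @return similarity in \[0, 1\].
#' @export
term_similarity <- function(a1, a2, corpus, aspect = "BP") {
  ont <- corpus$ontology
  if (!a1 %in% ont$ids || !a2 %in% ont$ids) {
    stop("term not in ontology: ", if (!a1 %in% ont$ids) a1 else a2)
  }
  a <- corpus$aspects[[aspect]]
  p <- a$p
  common <- intersect(ont$ancestors[[a1]], ont$ancestors[[a2]])
  common <- common[common %in% names(p) & p[common] > 0]
  if (!length(common)) return(0)
  p1 <- if (a1 %in% names(p)) p[[a1]] else 0
  p2 <- if (a2 %in% names(p)) p[[a2]] else 0
  denom <- log(p1) + log(p2)
  if (denom == 0) return(0)          # both terms universal
  pc <- p[common]
  vals <- (2 * log(pc) / denom) * (1 - pc)
  vals[!is.finite(vals)] <- 0        # -Inf denominator (unused query term)
  max(0, vals)
}

# Similarity between two proteins from their direct annotation sets:
# best-match average (default) or max over term pairs.  NA when either
# protein has no direct annotation in the aspect.
protein_pair_similarity <- function(p1, p2, corpus, aspect = "BP",
                                    method = c("bma", "max"), cache = NULL) {
  method <- match.arg(method)
  a <- corpus$aspects[[aspect]]
  t1 <- a$direct[[p1]]; t2 <- a$direct[[p2]]
  if (is.null(t1) || is.null(t2)) return(NA_real_)
  sim <- matrix(0, length(t1), length(t2))
  for (i in seq_along(t1)) for (j in seq_along(t2)) {
    if (!is.null(cache)) {
      key <- if (t1[i] < t2[j]) paste0(t1[i], "|", t2[j]) else paste0(t2[j], "|", t1[i])
      v <- cache[[key]]
      if (is.null(v)) {
        v <- term_similarity(t1[i], t2[j], corpus, aspect)
        cache[[key]] <- v
      }
      sim[i, j] <- v
    } else {
      sim[i, j] <- term_similarity(t1[i], t2[j], corpus, aspect)
    }
  }
  if (method == "max") return(max(sim))
  (mean(apply(sim, 1L, max)) + mean(apply(sim, 2L, max))) / 2
}

# mean pairwise similarity over annotated pairs within one set; NA if no pair
set_pair_similarity <- function(members, corpus, aspect, method, cache) {
  a <- corpus$aspects[[aspect]]
  ann <- intersect(members, names(a$direct))
  if (length(ann) < 2L) return(c(mean = NA_real_, n_pairs = 0))
  prs <- utils::combn(ann, 2L)
  vals <- vapply(seq_len(ncol(prs)), function(k)
    protein_pair_similarity(prs[1L, k], prs[2L, k], corpus, aspect, method, cache), 0)
  c(mean = mean(vals), n_pairs = ncol(prs))
}

#' Co-annotation score of a clustering
#'
#' The annotation score of a cluster is the mean relevance similarity over
#' all its annotated protein pairs; the clustering score on one aspect is
#' the size-weighted mean over scoreable clusters; the co-annotation score
#' is the geometric mean of the biological-process and molecular-function
#' clustering scores.
#'
#' @param clustering `hunter_clustering` or list of character vectors.
#' @param corpus `annotation_corpus` with BP and MF annotations.
#' @param weighted weight cluster scores by cluster size (default) or not.
#' @param method protein-pair similarity combination ("bma" or "max").
#' @return list: `score` (geometric mean), per-aspect clustering scores.
#' @export
coannotation_score <- function(clustering, corpus, weighted = TRUE,
                               method = "bma") {
  mods <- if (inherits(clustering, "hunter_clustering")) clustering$modules else clustering
  cache <- new.env(parent = emptyenv())
  aspect_scores <- c(BP = NA_real_, MF = NA_real_)
  any_pair <- FALSE
  for (asp in c("BP", "MF")) {
    if (is.null(corpus$aspects[[asp]])) next
    per <- vapply(mods, set_pair_similarity, c(mean = 0, n_pairs = 0),
                  corpus = corpus, aspect = asp, method = method, cache = cache)
    ok <- !is.na(per["mean", ])
    if (!any(ok)) next
    any_pair <- TRUE
    wts <- if (weighted) lengths(mods)[ok] else rep(1, sum(ok))
    aspect_scores[[asp]] <- sum(per["mean", ok] * wts) / sum(wts)
  }
  if (!any_pair) stop("no annotated protein pair in any cluster")
  list(score = sqrt(prod(aspect_scores)), aspect_scores = aspect_scores)
}

#' Co-localization score of a clustering
#'
#' For each cluster, the plurality location count max_k |C_j ∩ O_k| is
#' summed over clusters and normalized by the total clustered protein count
#' sum_j |C_j| (proteins absent from every location stay in the
#' denominator): the fraction of clustered proteins co-localized with their
#' cluster's plurality location.
#'
#' @param clustering `hunter_clustering` or list of character vectors.
#' @param loc named list location -> proteins (see [read_localization()]).
#' @return score in \[0, 1\].
#' @export
colocalization_score <- function(clustering, loc) {
  mods <- if (inherits(clustering, "hunter_clustering")) clustering$modules else clustering
  if (!length(loc)) stop("empty localization data")
  if (!any(unlist(mods) %in% unlist(loc))) stop("no cluster protein has localization data")
  num <- sum(vapply(mods, function(cl)
    max(vapply(loc, function(o) length(intersect(cl, o)), 0L)), 0L))
  num / sum(lengths(mods))
}

#' Average pairwise semantic similarity of a collection of vertex sets
#'
#' Pools all unordered annotated protein pairs occurring within the member
#' sets of the collection and returns their mean relevance similarity.
#' Applied to module seeds, final modules and the whole vertex set, it
#' quantifies the nesting of annotation coherence (seeds tightest, whole
#' network loosest).
#'
#' @param sets list of character vectors.
#' @param corpus `annotation_corpus`.
#' @param aspect ontology aspect.
#' @param method protein-pair similarity combination.
#' @return mean similarity in \[0, 1\].
#' @export
average_similarity <- function(sets, corpus, aspect = "BP", method = "bma") {
  cache <- new.env(parent = emptyenv())
  tot <- 0; npairs <- 0
  for (s in sets) {
    r <- set_pair_similarity(s, corpus, aspect, method, cache)
    if (!is.na(r[["mean"]])) {
      tot <- tot + r[["mean"]] * r[["n_pairs"]]
      npairs <- npairs + r[["n_pairs"]]
    }
  }
  if (npairs == 0) stop("no annotated pair in any set")
  tot / npairs
}

#' Match a clustering against a gold-standard complex catalogue
#'
#' Each complex is treated as a term over the protein universe; a cluster
#' matches a complex when their hypergeometric overlap p-value is below
#' alpha.  Recall: fraction of complexes matched by at least one cluster;
#' precision: fraction of clusters matching at least one complex; F:
#' harmonic mean.
#'
#' @param clustering `hunter_clustering` or list of character vectors.
#' @param catalogue named list complex -> proteins.
#' @param universe background protein set (e.g. the network vertex set);
#'   default: union of catalogue and clustering proteins.
#' @param alpha p-value cutoff, default 1e-4.
#' @return list: matched (cluster count), precision, recall, f.
#' @export
match_gold_standard <- function(clustering, catalogue, universe = NULL,
                                alpha = 1e-4) {
  mods <- if (inherits(clustering, "hunter_clustering")) clustering$modules else clustering
  if (!length(catalogue)) stop("empty complex catalogue")
  if (is.null(universe)) universe <- union(unlist(mods), unlist(catalogue))
  N <- length(universe)
  cat_u <- lapply(catalogue, intersect, universe)
  cat_u <- cat_u[lengths(cat_u) > 0L]
  cluster_hit <- logical(length(mods))
  complex_hit <- setNames(logical(length(cat_u)), names(cat_u))
  for (i in seq_along(mods)) {
    cl <- intersect(mods[[i]], universe)
    n <- length(cl)
    if (n == 0L) next
    for (cx in names(cat_u)) {
      x <- length(intersect(cl, cat_u[[cx]]))
      if (x == 0L) next
      p <- enrichment_pvalue(N, length(cat_u[[cx]]), n, x)
      if (p < alpha) { cluster_hit[i] <- TRUE; complex_hit[[cx]] <- TRUE }
    }
  }
  precision <- if (length(mods)) mean(cluster_hit) else 0
  recall <- if (length(complex_hit)) mean(complex_hit) else 0
  f <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  list(matched = sum(cluster_hit), precision = precision, recall = recall, f = f)
}
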