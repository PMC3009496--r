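#' @importFrom stats cor phyper setNames rnorm runif
#' @importFrom utils combn head
NULL

#' Build a validated weighted PPI network
#'
#' Constructs an undirected simple [igraph::igraph] graph whose edges carry an
#' interaction confidence score in (0, 1].  Self-loops are rejected; duplicate
#' edges are collapsed keeping the maximum score (confidence scores are
#' probabilities, so keeping the maximum is the conservative choice for
#' q-connectivity) with a warning.
#'
#' @param edges data.frame with columns `from`, `to` (character) and
#'   optionally `weight` (numeric in (0,1]; missing weights default to 1).
#' @return igraph object with vertex names and an edge attribute `weight`.
#' @export
ppi_network <- function(edges) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 2)
  from <- as.character(edges[[1]])
  to <- as.character(edges[[2]])
  w <- if (ncol(edges) >= 3) as.numeric(edges[[3]]) else rep(1, length(from))
  w[is.na(w)] <- 1
  if (any(from == to)) {
    stop("self-loop edge(s): ", paste(unique(from[from == to]), collapse = ", "))
  }
  if (any(w <= 0 | w > 1)) {
    bad <- which(w <= 0 | w > 1)[1L]
    stop(sprintf("edge weight out of (0,1]: %s-%s weight %g", from[bad], to[bad], w[bad]))
  }
  # canonical unordered key for duplicate detection
  key <- ifelse(from < to, paste(from, to, sep = "\r"), paste(to, from, sep = "\r"))
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate edge(s); keeping maximum score")
    w <- tapply(w, key, max)[unique(key)]
    keep <- !duplicated(key)
    from <- from[keep]; to <- to[keep]
  }
  # preserve first-appearance vertex order for deterministic iteration
  verts <- unique(c(rbind(from, to)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = as.numeric(w)),
    directed = FALSE, vertices = verts
  )
  g
}

#' Read a weighted PPI edge list
#'
#' Reads a tab-delimited edge list (`proteinA proteinB [score]`) or the SIF
#' dialect (`proteinA pp proteinB [score]`).  A missing score column defaults
#' to 1.0, i.e. an unweighted network.  Input vertex order is preserved.
#'
#' @param path file path.
#' @param dialect `"tab"` (default) or `"sif"`.
#' @return weighted network as built by [ppi_network()].
#' @export
read_ppi <- function(path, dialect = c("tab", "sif")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty PPI file: ", path)
  parts <- strsplit(lines, "[\t ]+")
  min_cols <- if (dialect == "sif") 3L else 2L
  n <- lengths(parts)
  if (any(n < min_cols)) {
    stop("malformed line ", which(n < min_cols)[1L], " in ", path)
  }
  if (dialect == "sif") {
    from <- vapply(parts, `[`, "", 1L)
    to <- vapply(parts, `[`, "", 3L)
    score <- vapply(parts, function(p) if (length(p) >= 4L) p[4L] else NA_character_, "")
  } else {
    from <- vapply(parts, `[`, "", 1L)
    to <- vapply(parts, `[`, "", 2L)
    score <- vapply(parts, function(p) if (length(p) >= 3L) p[3L] else NA_character_, "")
  }
  w <- suppressWarnings(as.numeric(score))
  if (any(!is.na(score) & is.na(w))) {
    stop("non-numeric score on line ", which(!is.na(score) & is.na(w))[1L], " in ", path)
  }
  w[is.na(w)] <- 1
  ppi_network(data.frame(from = from, to = to, weight = w))
}

#' Largest connected component of a network
#'
#' Returns the induced subgraph on the maximal connected component; ties on
#' size are broken toward the component containing the lexicographically
#' smallest vertex name.
#'
#' @param net igraph network.
#' @return igraph network (induced subgraph).
#' @export
maximal_connected_component <- function(net) {
  if (igraph::vcount(net) == 0L) stop("empty network")
  comp <- igraph::components(net)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # smallest member vertex name decides
    mins <- vapply(best, function(k) {
      min(igraph::V(net)$name[comp$membership == k])
    }, "")
    best <- best[order(mins)][1L]
  }
  igraph::induced_subgraph(net, which(comp$membership == best))
}

#' Read an expression matrix
#'
#' Tab-delimited file, first column a gene identifier, remaining columns
#' numeric expression values over a shared condition axis.  All rows must
#' have the same number of conditions.
#'
#' @param path file path.
#' @return numeric matrix, genes in rows (rownames), conditions in columns.
#' @export
read_expression <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty expression file: ", path)
  parts <- strsplit(lines, "\t")
  n <- lengths(parts)
  if (length(unique(n)) != 1L) {
    stop("ragged expression file: row ", which(n != n[1L])[1L], " has ", n[which(n != n[1L])[1L]],
         " fields, expected ", n[1L])
  }
  genes <- vapply(parts, `[`, "", 1L)
  if (anyDuplicated(genes)) stop("duplicate gene id: ", genes[duplicated(genes)][1L])
  vals <- lapply(parts, function(p) suppressWarnings(as.numeric(p[-1L])))
  for (i in seq_along(vals)) {
    if (anyNA(vals[[i]])) {
      stop("non-numeric value at row ", i, " column ", which(is.na(vals[[i]]))[1L] + 1L)
    }
  }
  m <- do.call(rbind, vals)
  rownames(m) <- genes
  colnames(m) <- paste0("cond", seq_len(ncol(m)))
  m
}

read_keyed_sets <- function(path, what) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty ", what, " file: ", path)
  parts <- strsplit(lines, "\t")
  if (any(lengths(parts) < 2L)) {
    stop("malformed line ", which(lengths(parts) < 2L)[1L], " in ", path)
  }
  key <- vapply(parts, `[`, "", 1L)
  member <- vapply(parts, `[`, "", 2L)
  lapply(split(member, factor(key, levels = unique(key))), unique)
}

#' Read localization data (`location<TAB>protein` records)
#' @param path file path.
#' @return named list: location -> character vector of proteins.
#' @export
read_localization <- function(path) read_keyed_sets(path, "localization")

#' Read a gold-standard complex catalogue (`complex_id<TAB>protein` records)
#' @param path file path.
#' @return named list: complex id -> character vector of proteins
#'   (duplicates within a complex are collapsed).
#' @export
read_complexes <- function(path) read_keyed_sets(path, "complex catalogue")

#' Write a clustering
#'
#' One module per line: `module_id<TAB>seed_vertex<TAB>member1,member2,...`.
#'
#' @param clustering a `hunter_clustering` (see [run_pipeline()]) or a plain
#'   list of character vectors.
#' @param path output path.
#' @export
write_clustering <- function(clustering, path) {
  mods <- if (inherits(clustering, "hunter_clustering")) clustering$modules else clustering
  seeds <- if (inherits(clustering, "hunter_clustering")) clustering$seed_vertex else NULL
  ids <- names(mods)
  if (is.null(ids)) ids <- paste0("module_", seq_along(mods))
  lines <- vapply(seq_along(mods), function(i) {
    sv <- if (!is.null(seeds) && length(seeds) >= i && nzchar(seeds[i])) seeds[i] else "-"
    paste(ids[i], sv, paste(mods[[i]], collapse = ","), sep = "\t")
  }, "")
  writeLines(lines, path)
}

#' Read a clustering written by [write_clustering()]
#' @param path file path.
#' @return `hunter_clustering` object.
#' @export
read_clustering <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty clustering file: ", path)
  parts <- strsplit(lines, "\t")
  if (any(lengths(parts) < 3L)) {
    stop("malformed line ", which(lengths(parts) < 3L)[1L], " in ", path)
  }
  mods <- lapply(parts, function(p) unique(strsplit(p[3L], ",", fixed = TRUE)[[1L]]))
  names(mods) <- vapply(parts, `[`, "", 1L)
  new_clustering(mods, seed_vertex = vapply(parts, `[`, "", 2L))
}

new_clustering <- function(modules, seed_vertex = rep("-", length(modules)), log = list()) {
  if (is.null(names(modules)) && length(modules)) {
    names(modules) <- paste0("module_", seq_along(modules))
  }
  structure(list(modules = modules, seed_vertex = seed_vertex, log = log),
            class = "hunter_clustering")
}

#' @export
print.hunter_clustering <- function(x, ...) {
  cat("hunter clustering:", length(x$modules), "modules,",
      length(unique(unlist(x$modules))), "unique proteins\n")
  szs <- lengths(x$modules)
  if (length(szs)) cat("module sizes:", paste(utils::head(szs, 10L), collapse = " "),
                       if (length(szs) > 10L) "..." else "", "\n")
  invisible(x)
}
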