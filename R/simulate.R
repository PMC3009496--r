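#' Planted-module benchmark model
#'
#' Parameters of the synthetic benchmark: modules are planted as dense
#' blocks of high-confidence edges (a functional module induces a dense
#' region of the interactome); the background is a sparse low-confidence
#' random graph; genes of one module share a latent expression profile
#' (proteins of one complex are co-expressed), observed with Gaussian noise.
#' Decoy edges connect a module member to an anticorrelated background gene,
#' emulating false-positive interactions that expression filtering should
#' remove.
#'
#' @param n_modules number of planted modules.
#' @param size_range inclusive module-size range (sampled uniformly).
#' @param within_density edge probability inside a module.
#' @param within_weight_range confidence-score range for within-module edges.
#' @param background_density edge probability between non-module pairs.
#' @param background_weight_range confidence-score range for background edges.
#' @param n_background number of background (non-module) vertices.
#' @param overlap_frac fraction of each module's vertices shared with the
#'   previous module (overlapping modules exercise the merge stage).
#' @param within_correlation target mean within-module expression
#'   correlation; observation noise is calibrated as
#'   noise_sd = sqrt(1/target - 1) so that two noisy copies of the same
#'   standard-normal latent profile correlate at the target on average.
#' @param n_conditions expression conditions (>= 3).
#' @param n_decoy_edges anticorrelated decoy edges to plant.
#' @return list of class `planted_model`.
#' @export
planted_model <- function(n_modules = 3L, size_range = c(8L, 12L),
                          within_density = 0.9,
                          within_weight_range = c(0.9, 0.99),
                          background_density = 0.01,
                          background_weight_range = c(0.1, 0.5),
                          n_background = 40L, overlap_frac = 0,
                          within_correlation = 0.9, n_conditions = 20L,
                          n_decoy_edges = 0L) {
  stopifnot(within_density >= 0, within_density <= 1,
            background_density >= 0, background_density <= 1,
            all(within_weight_range > 0), all(within_weight_range <= 1),
            all(background_weight_range > 0), all(background_weight_range <= 1),
            n_conditions >= 3L, within_correlation > 0, within_correlation <= 1)
  structure(as.list(environment()), class = "planted_model")
}

#' Generate a planted-module weighted network
#'
#' Modules are blocks of Bernoulli(within_density) edges with weights drawn
#' uniformly from the within range (a spanning path is forced so every
#' planted module is connected); all other pairs get Bernoulli
#' (background_density) edges with background weights.  Decoy edges attach a
#' module member to a dedicated background vertex that
#' [generate_expression()] will profile anticorrelated to the module.
#'
#' @param model `planted_model`.
#' @param seed integer RNG seed; the generated network is bit-identical
#'   given the seed.
#' @return list: `net` (igraph), `truth` (list of module member vectors),
#'   `decoy_edges` (2-column matrix), `module_of` (latent block per vertex).
#' @export
generate_network <- function(model, seed = 1L) {
  set.seed(seed)
  sizes <- sample(seq(model$size_range[1L], model$size_range[2L]),
                  model$n_modules, replace = TRUE)
  truth <- list(); module_of <- integer(0)
  nxt <- 1L
  prev <- character(0)
  for (m in seq_len(model$n_modules)) {
    n_share <- if (m > 1L) min(floor(model$overlap_frac * sizes[m]), length(prev)) else 0L
    shared <- if (n_share > 0L) sample(prev, n_share) else character(0)
    fresh <- sprintf("P%03d", seq(nxt, nxt + sizes[m] - n_share - 1L))
    nxt <- nxt + sizes[m] - n_share
    truth[[m]] <- sort(c(shared, fresh))
    prev <- truth[[m]]
  }
  names(truth) <- sprintf("planted_%d", seq_along(truth))
  bg <- sprintf("B%03d", seq_len(model$n_background))
  verts <- c(unique(unlist(truth)), bg)
  module_of <- setNames(rep(0L, length(verts)), verts)
  for (m in seq_along(truth)) module_of[truth[[m]]] <- m
  ew <- new.env(parent = emptyenv())
  add_edge <- function(a, b, w) {
    key <- if (a < b) paste(a, b, sep = "\r") else paste(b, a, sep = "\r")
    if (is.null(ew[[key]])) ew[[key]] <- w else ew[[key]] <- max(ew[[key]], w)
  }
  runifw <- function(n, rng) stats::runif(n, rng[1L], rng[2L])
  for (m in seq_along(truth)) {
    mem <- truth[[m]]
    # spanning path guarantees connectivity
    for (i in seq_len(length(mem) - 1L)) {
      add_edge(mem[i], mem[i + 1L], runifw(1L, model$within_weight_range))
    }
    prs <- utils::combn(mem, 2L)
    for (k in seq_len(ncol(prs))) {
      if (stats::runif(1) < model$within_density) {
        add_edge(prs[1L, k], prs[2L, k], runifw(1L, model$within_weight_range))
      }
    }
  }
  # background edges: any pair not inside the same module
  allv <- verts
  for (i in seq_len(length(allv) - 1L)) {
    for (j in (i + 1L):length(allv)) {
      a <- allv[i]; b <- allv[j]
      same <- module_of[a] != 0L && module_of[a] == module_of[b]
      if (!same && stats::runif(1) < model$background_density) {
        add_edge(a, b, runifw(1L, model$background_weight_range))
      }
    }
  }
  # decoy edges: module member -- dedicated anticorrelated background vertex
  decoys <- matrix(character(0), ncol = 2L)
  if (model$n_decoy_edges > 0L) {
    dv <- sprintf("D%03d", seq_len(model$n_decoy_edges))
    anchors <- sample(unlist(truth), model$n_decoy_edges, replace = TRUE)
    for (k in seq_len(model$n_decoy_edges)) {
      add_edge(anchors[k], dv[k], runifw(1L, model$within_weight_range))
    }
    decoys <- cbind(anchors, dv)
    verts <- c(verts, dv)
    module_of <- c(module_of, setNames(-module_of[anchors], dv))
  }
  keys <- ls(ew)
  ab <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  net <- igraph::graph_from_data_frame(
    data.frame(from = ab[, 1L], to = ab[, 2L],
               weight = vapply(keys, function(k) ew[[k]], 0)),
    directed = FALSE, vertices = sort(verts))
  list(net = net, truth = truth, decoy_edges = unname(decoys),
       module_of = module_of)
}

#' Generate expression profiles for a planted network
#'
#' Each module has a standard-normal latent profile over the conditions;
#' member genes observe it with additive Gaussian noise calibrated to the
#' model's target within-module correlation.  Background genes get
#' independent latent profiles.  Decoy vertices observe the negated latent
#' profile of their anchor's module, so decoy edges join anticorrelated
#' genes.  Vertices shared by two modules observe the profile of the module
#' that planted them first.
#'
#' @param model `planted_model`.
#' @param sim output of [generate_network()].
#' @param seed integer RNG seed.
#' @return numeric matrix genes x conditions.
#' @export
generate_expression <- function(model, sim, seed = 1L) {
  set.seed(seed + 1L)
  noise_sd <- sqrt(1 / model$within_correlation - 1)
  nc <- model$n_conditions
  verts <- names(sim$module_of)
  latent <- matrix(stats::rnorm(length(sim$truth) * nc), nrow = length(sim$truth))
  prof <- matrix(NA_real_, nrow = length(verts), ncol = nc,
                 dimnames = list(verts, paste0("cond", seq_len(nc))))
  for (v in verts) {
    m <- sim$module_of[[v]]
    base <- if (m > 0L) latent[m, ]
            else if (m < 0L) -latent[-m, ]
            else stats::rnorm(nc)
    prof[v, ] <- base + noise_sd * stats::rnorm(nc)
  }
  prof
}

#' Generate a toy ontology and annotation corpus for a planted truth
#'
#' Builds, for the BP and MF aspects, a root term and one leaf term per
#' planted module; every module member is annotated to its module's leaf
#' (subject to `dropout`), and `contamination` background proteins per
#' module are annotated spuriously.  With `nested = TRUE` each module also
#' gets a deeper core term annotating a random core subset of its members,
#' giving the nested annotation coherence (core tighter than module tighter
#' than background) that seed/module/network similarity comparisons probe.
#'
#' @param sim output of [generate_network()].
#' @param dropout probability that a member's annotation is omitted.
#' @param contamination number of spurious background annotations per
#'   module term.
#' @param nested add per-module core terms (see Details).
#' @param core_frac fraction of members in a nested core.
#' @param seed integer RNG seed.
#' @return list: `obo` and `gaf` (character vectors of file lines),
#'   `cores` (list of core member sets when nested).
#' @export
generate_ontology <- function(sim, dropout = 0, contamination = 0L,
                              nested = FALSE, core_frac = 0.4, seed = 1L) {
  set.seed(seed + 2L)
  roots <- c(BP = "GO:0008150", MF = "GO:0003674")
  ns <- c(BP = "biological_process", MF = "molecular_function")
  obo <- c("format-version: 1.2")
  gaf <- c("!gaf-version: 2.0")
  cores <- vector("list", length(sim$truth))
  names(cores) <- names(sim$truth)
  bg <- names(sim$module_of)[sim$module_of == 0L]
  term_id <- function(asp, m, core = FALSE) {
    sprintf("GO:%s%02d%02d", if (core) "11" else "10", match(asp, names(roots)), m)
  }
  for (asp in names(roots)) {
    obo <- c(obo, "", "[Term]", paste0("id: ", roots[[asp]]),
             paste0("name: ", ns[[asp]], " root"), paste0("namespace: ", ns[[asp]]))
  }
  gaf_line <- function(protein, term, asp) {
    paste("SYN", protein, protein, "", term, "SYN:ref", "IEA", "",
          c(BP = "P", MF = "F")[[asp]], "", "", "protein", "taxon:0", "20200101",
          "SYN", sep = "\t")
  }
  for (m in seq_along(sim$truth)) {
    mem <- sim$truth[[m]]
    keep <- mem[stats::runif(length(mem)) >= dropout]
    core <- if (nested) sort(sample(mem, max(2L, round(core_frac * length(mem))))) else character(0)
    cores[[m]] <- core
    for (asp in names(roots)) {
      tid <- term_id(asp, m)
      obo <- c(obo, "", "[Term]", paste0("id: ", tid),
               sprintf("name: planted module %d %s", m, asp),
               paste0("namespace: ", ns[[asp]]),
               paste0("is_a: ", roots[[asp]]))
      if (nested) {
        cid <- term_id(asp, m, core = TRUE)
        obo <- c(obo, "", "[Term]", paste0("id: ", cid),
                 sprintf("name: planted core %d %s", m, asp),
                 paste0("namespace: ", ns[[asp]]), paste0("is_a: ", tid))
      }
      for (pr in keep) {
        tgt <- if (nested && pr %in% core) term_id(asp, m, core = TRUE) else tid
        gaf <- c(gaf, gaf_line(pr, tgt, asp))
      }
      if (contamination > 0L && length(bg)) {
        for (pr in sample(bg, min(contamination, length(bg)))) {
          gaf <- c(gaf, gaf_line(pr, tid, asp))
        }
      }
    }
  }
  # background proteins annotated to the root only: present in the corpus,
  # uninformative for similarity
  for (pr in bg) for (asp in names(roots)) gaf <- c(gaf, gaf_line(pr, roots[[asp]], asp))
  list(obo = obo, gaf = gaf, cores = cores)
}

#' Generate localization sets for a planted truth
#'
#' One location per planted module containing exactly its members, plus a
#' catch-all location for background vertices.
#'
#' @param sim output of [generate_network()].
#' @return named list location -> proteins.
#' @export
generate_localization <- function(sim) {
  loc <- sim$truth
  names(loc) <- sprintf("location_%d", seq_along(loc))
  bg <- names(sim$module_of)[sim$module_of <= 0L]
  if (length(bg)) loc$location_bg <- bg
  loc
}

#' Generate a gold-standard catalogue from a planted truth
#'
#' @param sim output of [generate_network()].
#' @param dropout per-protein probability of omission from its complex.
#' @param contamination contaminant background proteins added per complex.
#' @param seed integer RNG seed.
#' @return named list complex -> proteins.
#' @export
generate_gold <- function(sim, dropout = 0, contamination = 0L, seed = 1L) {
  set.seed(seed + 3L)
  bg <- names(sim$module_of)[sim$module_of == 0L]
  out <- lapply(sim$truth, function(mem) {
    keep <- mem[stats::runif(length(mem)) >= dropout]
    if (contamination > 0L && length(bg)) {
      keep <- c(keep, sample(bg, min(contamination, length(bg))))
    }
    sort(unique(keep))
  })
  out <- out[lengths(out) > 0L]
  names(out) <- sprintf("complex_%d", seq_along(out))
  out
}

#' Simulation presets
#'
#' `easy`: 3 well-separated modules of 8-12 vertices with within-module
#' confidence scores in 0.9-0.99, within-module density 0.9, background
#' density 0.01 and 20 anticorrelated decoy edges.  `overlap`: 4 modules
#' with 10% shared vertices.  `hard`: weaker weights, denser background,
#' noisier expression.
#'
#' @param preset "easy", "overlap" or "hard".
#' @param seed integer RNG seed.
#' @return list: model, net, truth, decoy_edges, module_of, expr, loc, gold.
#' @export
simulate_preset <- function(preset = c("easy", "overlap", "hard"), seed = 1L) {
  preset <- match.arg(preset)
  model <- switch(preset,
    easy = planted_model(n_modules = 3L, size_range = c(8L, 12L),
                         within_density = 0.9, within_weight_range = c(0.9, 0.99),
                         background_density = 0.01, n_background = 40L,
                         within_correlation = 0.9, n_decoy_edges = 20L),
    overlap = planted_model(n_modules = 4L, size_range = c(8L, 12L),
                            within_density = 0.9, within_weight_range = c(0.9, 0.99),
                            background_density = 0.01, n_background = 40L,
                            overlap_frac = 0.1, within_correlation = 0.9,
                            n_decoy_edges = 10L),
    hard = planted_model(n_modules = 5L, size_range = c(6L, 14L),
                         within_density = 0.7, within_weight_range = c(0.7, 0.95),
                         background_density = 0.05, n_background = 60L,
                         within_correlation = 0.7, n_decoy_edges = 30L))
  sim <- generate_network(model, seed = seed)
  sim$model <- model
  sim$expr <- generate_expression(model, sim, seed = seed)
  sim$loc <- generate_localization(sim)
  sim$gold <- generate_gold(sim, seed = seed)
  sim
}

#' Write all files of a simulated benchmark to a directory
#'
#' Emits `ppi.tsv`, `expression.tsv`, `ontology.obo`, `annotations.gaf`,
#' `localization.tsv`, `gold_complexes.tsv` and `truth.tsv`; all parse back
#' through the package's readers.
#'
#' @param sim output of [simulate_preset()].
#' @param dir output directory (created if needed).
#' @param seed seed forwarded to the ontology generator.
#' @return invisibly, the vector of written paths.
#' @export
write_simulation <- function(sim, dir, seed = 1L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  el <- igraph::as_edgelist(sim$net)
  p <- function(f) file.path(dir, f)
  writeLines(paste(el[, 1L], el[, 2L],
                   format(igraph::E(sim$net)$weight, digits = 6), sep = "\t"),
             p("ppi.tsv"))
  writeLines(paste(rownames(sim$expr),
                   apply(sim$expr, 1L, function(r) paste(format(r, digits = 6), collapse = "\t")),
                   sep = "\t"), p("expression.tsv"))
  ont <- generate_ontology(sim, seed = seed)
  writeLines(ont$obo, p("ontology.obo"))
  writeLines(ont$gaf, p("annotations.gaf"))
  writeLines(unlist(lapply(names(sim$loc), function(k)
    paste(k, sim$loc[[k]], sep = "\t"))), p("localization.tsv"))
  writeLines(unlist(lapply(names(sim$gold), function(k)
    paste(k, sim$gold[[k]], sep = "\t"))), p("gold_complexes.tsv"))
  writeLines(unlist(lapply(names(sim$truth), function(k)
    paste(k, sim$truth[[k]], sep = "\t"))), p("truth.tsv"))
  invisible(vapply(c("ppi.tsv", "expression.tsv", "ontology.obo", "annotations.gaf",
                     "localization.tsv", "gold_complexes.tsv", "truth.tsv"), p, ""))
}
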