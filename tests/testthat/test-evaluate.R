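test_that("OBO parsing propagates annotations through is_a chains and multiple parents", {
  obo <- c("format-version: 1.2",
           "", "[Term]", "id: GO:r", "name: root", "namespace: biological_process",
           "", "[Term]", "id: GO:m1", "namespace: biological_process", "is_a: GO:r",
           "", "[Term]", "id: GO:m2", "namespace: biological_process", "is_a: GO:r",
           "", "[Term]", "id: GO:leaf", "namespace: biological_process",
           "is_a: GO:m1", "relationship: part_of GO:m2",
           "", "[Term]", "id: GO:dead", "namespace: biological_process",
           "is_a: GO:r", "is_obsolete: true")
  expect_warning(ont <- parse_obo(write_tmp(obo, ".obo")), "obsolete")
  expect_false("GO:dead" %in% ont$ids)
  # a term with two parents propagates to both lineages
  expect_setequal(ont$ancestors[["GO:leaf"]], c("GO:leaf", "GO:m1", "GO:m2", "GO:r"))
  corpus <- parse_annotations(write_tmp(c("p1\tGO:leaf\tBP", "p2\tGO:m1\tBP"), ".gaf"),
                              ont)
  a <- corpus$aspects$BP
  expect_setequal(a$propagated$p1, c("GO:leaf", "GO:m1", "GO:m2", "GO:r"))
  # p(root) = 1 and p never decreases child -> parent
  expect_equal(a$p[["GO:r"]], 1)
  expect_gte(a$p[["GO:m1"]], a$p[["GO:leaf"]])

  cyc <- c("[Term]", "id: GO:a", "namespace: biological_process", "is_a: GO:b",
           "", "[Term]", "id: GO:b", "namespace: biological_process", "is_a: GO:a")
  expect_error(parse_obo(write_tmp(cyc, ".obo")), "cyclic")
})

test_that("GAF dialect records are parsed and NOT qualifiers skipped", {
  obo <- c("[Term]", "id: GO:r", "namespace: biological_process",
           "", "[Term]", "id: GO:x", "namespace: biological_process", "is_a: GO:r")
  ont <- parse_obo(write_tmp(obo, ".obo"))
  gaf <- c("!gaf-version: 2.0",
           paste("DB", "p1", "p1", "", "GO:x", "ref", "IEA", "", "P", "", "",
                 "protein", "taxon:0", "20200101", "DB", sep = "\t"),
           paste("DB", "p2", "p2", "NOT", "GO:x", "ref", "IEA", "", "P", "", "",
                 "protein", "taxon:0", "20200101", "DB", sep = "\t"))
  corpus <- parse_annotations(write_tmp(gaf, ".gaf"), ont)
  expect_equal(names(corpus$aspects$BP$direct), "p1")
})

test_that("hypergeometric tail matches exact combinatorial sums", {
  # C(5,4) C(5,0) / C(10,4) = 5/210
  expect_equal(enrichment_pvalue(10, 5, 4, 4), 5 / 210)
  expect_equal(enrichment_pvalue(10, 5, 4, 0), 1)
  expect_error(enrichment_pvalue(10, 11, 4, 2), "inconsistent")
  set.seed(15)
  for (i in 1:200) {
    N <- sample(5:25, 1); M <- sample(1:N, 1); n <- sample(1:N, 1)
    x <- sample(0:min(n, M), 1)
    expect_equal(enrichment_pvalue(N, M, n, x), brute_hypergeom_tail(N, M, n, x),
                 tolerance = 1e-12)
  }
  # monotone decreasing in x at fixed (N, M, n)
  ps <- vapply(0:5, function(x) enrichment_pvalue(20, 8, 5, x), 0)
  expect_true(all(diff(ps) <= 0))
})

test_that("f_measure follows the enriched-term / enriched-cluster definitions", {
  corpus <- toy_corpus()
  # clusters exactly matching the two leaf extensions: specificity 1
  cl <- list(c("p1", "p2"), c("p3", "p4"))
  fm <- f_measure(cl, corpus, "BP", alpha = 0.05)
  expect_equal(fm$specificity, 1)
  # informative BP terms: GO:2 (p5,p1..p4), GO:3, GO:4 -> all enriched?
  expect_true(fm$sensitivity > 0)
  expect_equal(fm$f, 2 * fm$sensitivity * fm$specificity /
                 (fm$sensitivity + fm$specificity))
  # singleton random clusters cannot reach p < 1e-4 in a tiny corpus
  singles <- as.list(paste0("p", 1:6))
  fs <- f_measure(singles, corpus, "BP", alpha = 1e-4)
  expect_equal(fs$sensitivity, 0)
  expect_equal(fs$f, 0)
  expect_error(f_measure(list(), corpus, "BP"), "empty clustering")
})

test_that("harmonic mean arithmetic on a constructed half-sensitive fixture", {
  # corpus with two informative leaves; a clustering that retrieves exactly
  # one of them: sensitivity 1/2, specificity 1, F = 2/3
  obo <- c("[Term]", "id: GO:r", "namespace: biological_process",
           "", "[Term]", "id: GO:A", "namespace: biological_process", "is_a: GO:r",
           "", "[Term]", "id: GO:B", "namespace: biological_process", "is_a: GO:r")
  ont <- parse_obo(write_tmp(obo, ".obo"))
  ann <- c(paste0("a", 1:6, "\tGO:A\tBP"), paste0("b", 1:6, "\tGO:B\tBP"))
  corpus <- parse_annotations(write_tmp(ann, ".gaf"), ont)
  fm <- f_measure(list(paste0("a", 1:6)), corpus, "BP", alpha = 0.01)
  expect_equal(fm$sensitivity, 0.5)
  expect_equal(fm$specificity, 1)
  expect_equal(fm$f, 2 / 3)
})

test_that("term similarity is the Schlicker relevance maximum over common ancestors", {
  corpus <- toy_corpus()
  p <- corpus$aspects$BP$p
  # self-similarity = 1 - p(a)
  expect_equal(term_similarity("GO:3", "GO:3", corpus, "BP"), 1 - p[["GO:3"]])
  # symmetric
  expect_equal(term_similarity("GO:3", "GO:4", corpus, "BP"),
               term_similarity("GO:4", "GO:3", corpus, "BP"))
  # only common ancestor is the root (p = 1): similarity 0
  obo2 <- c("[Term]", "id: GO:r", "namespace: biological_process",
            "", "[Term]", "id: GO:A", "namespace: biological_process", "is_a: GO:r",
            "", "[Term]", "id: GO:B", "namespace: biological_process", "is_a: GO:r")
  ont2 <- parse_obo(write_tmp(obo2, ".obo"))
  c2 <- parse_annotations(write_tmp(c("p1\tGO:A\tBP", "p2\tGO:B\tBP"), ".gaf"), ont2)
  expect_equal(term_similarity("GO:A", "GO:B", c2, "BP"), 0)
  expect_error(term_similarity("GO:zzz", "GO:A", c2, "BP"), "not in ontology")
  # brute-force maximum over all common ancestors on the toy DAG
  ont <- corpus$ontology
  for (pair in list(c("GO:3", "GO:4"), c("GO:3", "GO:2"), c("GO:2", "GO:2"))) {
    common <- intersect(ont$ancestors[[pair[1]]], ont$ancestors[[pair[2]]])
    vals <- vapply(common, function(cc) {
      (2 * log(p[[cc]]) / (log(p[[pair[1]]]) + log(p[[pair[2]]]))) * (1 - p[[cc]])
    }, 0)
    expect_equal(term_similarity(pair[1], pair[2], corpus, "BP"), max(0, vals))
  }
})

test_that("co-annotation is the size-weighted geometric-mean score", {
  corpus <- toy_corpus()
  # identically annotated pair in both aspects scores sim(a,a) = 1 - p(a)
  cl <- list(c("p1", "p2"))
  coa <- coannotation_score(cl, corpus)
  pB <- corpus$aspects$BP$p[["GO:3"]]
  pM <- corpus$aspects$MF$p[["GO:6"]]
  expect_equal(coa$aspect_scores[["BP"]], 1 - pB)
  expect_equal(coa$aspect_scores[["MF"]], 1 - pM)
  expect_equal(coa$score, sqrt((1 - pB) * (1 - pM)))
  # hand-computed weighted mean over two clusters in BP
  cl2 <- list(c("p1", "p2"), c("p3", "p4", "p5"))
  s1 <- term_similarity("GO:3", "GO:3", corpus, "BP")
  s34 <- term_similarity("GO:4", "GO:4", corpus, "BP")
  s35 <- term_similarity("GO:4", "GO:2", corpus, "BP")
  exp_c2 <- mean(c(s34, s35, s35))
  expected_bp <- (2 * s1 + 3 * exp_c2) / 5
  coa2 <- coannotation_score(cl2, corpus)
  expect_equal(coa2$aspect_scores[["BP"]], expected_bp)
  expect_error(coannotation_score(list(c("q1", "q2")), corpus), "no annotated")
})

test_that("co-localization scores the plurality location fraction", {
  loc <- list(nuc = c("a", "b", "c"), cyt = c("d", "e"), er = c("b", "f"))
  expect_equal(colocalization_score(list(c("a", "b", "c")), loc), 1)
  # 4-cluster split 2/2 across locations contributes 2/4
  expect_equal(colocalization_score(list(c("a", "b", "d", "e")), loc), 0.5)
  # brute-force per-cluster max over all locations on a 3-cluster fixture
  cls <- list(c("a", "b"), c("d", "e", "f"), c("c", "f"))
  manual <- sum(vapply(cls, function(cl)
    max(vapply(loc, function(o) length(intersect(cl, o)), 0L)), 0L)) /
    sum(lengths(cls))
  expect_equal(colocalization_score(cls, loc), manual)
  expect_error(colocalization_score(cls, list()), "empty")
})

test_that("average similarity pools within-set pairs and matches flat enumeration", {
  corpus <- toy_corpus()
  # single identically annotated pair: 1 - p(leaf)
  expect_equal(average_similarity(list(c("p1", "p2")), corpus, "BP"),
               1 - corpus$aspects$BP$p[["GO:3"]])
  # flat enumeration over a 4-set collection
  sets <- list(c("p1", "p2", "p3"), c("p3", "p4"), c("p5", "p6"), "p7")
  pairs <- list(c("p1", "p2"), c("p1", "p3"), c("p2", "p3"), c("p3", "p4"),
                c("p5", "p6"))
  manual <- mean(vapply(pairs, function(pr)
    hunter:::protein_pair_similarity(pr[1], pr[2], corpus, "BP"), 0))
  expect_equal(average_similarity(sets, corpus, "BP"), manual)
  expect_error(average_similarity(list("p1"), corpus, "BP"), "no annotated pair")
})

test_that("gold-standard matching by hypergeometric overlap", {
  # complexes of size >= 4: a size-3 set in this universe bottoms out at
  # p = 1/C(30,3) > 1e-4 and could never match at the default cutoff
  cat <- list(c1 = c("a", "b", "c", "d"), c2 = c("e", "f", "g", "h"))
  universe <- c(letters[1:10], paste0("x", 1:20))
  # clustering identical to the catalogue
  gs <- match_gold_standard(cat, cat, universe = universe)
  expect_equal(gs$precision, 1)
  expect_equal(gs$recall, 1)
  expect_equal(gs$f, 1)
  # disjoint clustering
  gs2 <- match_gold_standard(list(paste0("x", 1:4)), cat, universe = universe)
  expect_equal(gs2$precision, 0)
  expect_equal(gs2$f, 0)
  # matches brute-force p-value screening on a noisy clustering
  noisy <- list(c("a", "b", "c", "x1"), c("e", "x2", "x3"))
  gs3 <- match_gold_standard(noisy, cat, universe = universe, alpha = 1e-3)
  hit <- vapply(noisy, function(cl) {
    any(vapply(cat, function(cx) {
      x <- length(intersect(cl, cx))
      x > 0 && brute_hypergeom_tail(length(universe), length(cx), length(cl), x) < 1e-3
    }, NA))
  }, NA)
  expect_equal(gs3$precision, mean(hit))
})
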