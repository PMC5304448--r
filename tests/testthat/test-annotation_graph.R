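# weight matrix of a planted two-block graph
block_graph <- function(n1 = 4, n2 = 4, w_in = 1, w_out = 0.05) {
  n <- n1 + n2
  w <- matrix(w_out, n, n)
  w[1:n1, 1:n1] <- w_in
  w[(n1 + 1):n, (n1 + 1):n] <- w_in
  diag(w) <- 0
  dimnames(w) <- list(sprintf("t%02d", 1:n), sprintf("t%02d", 1:n))
  structure(list(nodes = rownames(w), w = w), class = "term_graph")
}

test_that("projection weight equals the Jaccard of propagated gene sets", {
  dag <- onto_dag(c("r", "t1", "t2", "t3"),
                  list(r = character(0), t1 = "r", t2 = "r", t3 = "r"),
                  root = "r")
  corpus <- propagate(list(g1 = "t1", g2 = c("t1", "t2"), g3 = "t2",
                           g4 = "t3"), dag)
  g <- project_term_graph(corpus, term_set = c("t1", "t2", "t3"))
  expect_equal(g$w["t1", "t2"], 1 / 3)   # {g1,g2} vs {g2,g3}
  expect_equal(g$w["t1", "t3"], 0)       # disjoint
  # identical gene sets give weight 1
  corpus2 <- propagate(list(g1 = c("a", "b")),
                       onto_dag(c("r", "a", "b"),
                                list(r = character(0), a = "r", b = "r"),
                                root = "r"))
  g2 <- project_term_graph(corpus2, term_set = c("a", "b"))
  expect_equal(g2$w["a", "b"], 1)
  # oracle: set operations per pair on a random world
  w <- toy_world(3)
  tg <- project_term_graph(w$corpus)
  gene_sets <- lapply(tg$nodes, function(t)
    Filter(function(g) t %in% w$corpus$propagated[[g]],
           w$corpus$universe))
  for (i in seq_along(tg$nodes)) for (j in seq_along(tg$nodes)) {
    if (i == j) next
    inter <- length(intersect(gene_sets[[i]], gene_sets[[j]]))
    uni <- length(union(gene_sets[[i]], gene_sets[[j]]))
    expect_equal(tg$w[i, j], if (inter == 0) 0 else inter / uni,
                 tolerance = 1e-12)
  }
  expect_warning(project_term_graph(w$corpus,
                                    term_set = c(tg$nodes, "ghost")),
                 "dropped")
})

test_that("spectral_ncut separates components and handles edge cases", {
  g <- block_graph(w_out = 0)          # two disconnected cliques
  a <- spectral_ncut(g, 2, seed = 1)
  expect_equal(length(unique(a$cluster[1:4])), 1)
  expect_equal(length(unique(a$cluster[5:8])), 1)
  expect_equal(a$objective, 0)
  a1 <- spectral_ncut(g, 1, seed = 1)
  expect_true(all(a1$cluster == 1))
  expect_equal(a1$objective, 0)
  expect_error(spectral_ncut(g, 9, seed = 1), "exceeds")
})

test_that("spectral_ncut attains the exhaustive 2-way minimum on planted graphs", {
  for (seed in 1:20) {
    set.seed(seed)
    n1 <- sample(3:5, 1); n2 <- sample(3:5, 1)
    g <- block_graph(n1, n2, w_in = 1, w_out = 0.05)
    # jitter weights to break symmetry
    jit <- matrix(stats::runif(nrow(g$w)^2, 0, 0.02), nrow(g$w))
    g$w <- g$w + (jit + t(jit)) * (g$w > 0)
    a <- spectral_ncut(g, 2, seed = seed)
    expect_equal(a$objective, oracle_min_ncut2(g$w), tolerance = 1e-8)
    expect_equal(a$objective, oracle_ncut(g$w, a$cluster),
                 tolerance = 1e-12)
  }
})

test_that("ncut objective beats random same-k partitions", {
  w <- toy_world(7, n_genes = 14)
  g <- project_term_graph(w$corpus)
  a <- spectral_ncut(g, 3, seed = 2)
  set.seed(99)
  for (i in 1:100) {
    rnd <- sample(1:3, length(g$nodes), replace = TRUE)
    if (length(unique(rnd)) < 3) next
    expect_lte(a$objective, oracle_ncut(g$w, rnd) + 1e-9)
  }
})

test_that("recursive_split obeys the cluster-count identity and locality", {
  g <- block_graph(6, 6, w_in = 1, w_out = 0.01)
  base <- spectral_ncut(g, 2, seed = 1)
  split <- recursive_split(g, 2, list(c(1, 2)), seed = 1)
  expect_equal(split$k, 2 - 1 + 2)
  # untouched cluster keeps its membership
  rank_ids <- as.integer(names(sort(table(base$cluster),
                                    decreasing = TRUE)))
  untouched <- names(base$cluster)[base$cluster == rank_ids[2]]
  expect_equal(length(unique(split$cluster[untouched])), 1)
  # empty split list identical to plain clustering
  expect_equal(recursive_split(g, 2, list(), seed = 1)$cluster,
               spectral_ncut(g, 2, seed = 1)$cluster)
  expect_error(recursive_split(g, 2, list(c(1, 50)), seed = 1),
               "smaller than sub_k")
  # the study's GO plan arithmetic: 100 - 2 + 33 + 9 = 140
  expect_equal(100 - 2 + 33 + 9, 140)
})

test_that("cluster randomization null preserves sizes; degenerate clusters", {
  world <- make_planted_corpus(synthetic_config(n_genes = 80, n_modules = 4,
                                                seed = 2))
  ic_b <- compute_ic(world$cmpo_corpus, world$cmpo_dag)
  g <- project_term_graph(world$go_corpus)
  a <- spectral_ncut(g, 4, seed = 1)
  res <- cluster_cross_ontology_similarity(a, world$go_corpus,
                                           world$cmpo_corpus,
                                           world$cmpo_dag, ic_b,
                                           n_rand = 20, seed = 1)
  expect_setequal(res$size, as.integer(table(a$cluster)))
  expect_true(all(res$p[!res$excluded] > 0 & res$p[!res$excluded] <= 1))
  # identical single B-annotation set across genes: p = 1
  dagA <- onto_dag(c("r", "a1", "a2"),
                   list(r = character(0), a1 = "r", a2 = "r"), root = "r")
  dagB <- onto_dag(c("rb", "b1", "b2"),
                   list(rb = character(0), b1 = "rb", b2 = "rb"),
                   root = "rb")
  corpA <- propagate(list(g1 = "a1", g2 = "a2"), dagA)
  corpB <- propagate(list(g1 = c("b1", "b2"), g2 = c("b1", "b2")), dagB)
  icB <- compute_ic(corpB, dagB)
  assign <- structure(list(cluster = c(a1 = 1L, a2 = 2L), k = 2L,
                           objective = 0, seed = 1L),
                      class = "cluster_assignment")
  resc <- cluster_cross_ontology_similarity(assign, corpA, corpB, dagB,
                                            icB, n_rand = 30, seed = 1,
                                            max_coverage = 1)
  expect_true(all(resc$p == 1))
  # cluster linked to < 2 B-terms is excluded
  corpB1 <- propagate(list(g1 = "b1", g2 = "b1"), dagB)
  icB1 <- compute_ic(corpB1, dagB)
  res1 <- cluster_cross_ontology_similarity(assign, corpA, corpB1, dagB,
                                            icB1, n_rand = 10, seed = 1)
  expect_true(all(res1$excluded))
})

test_that("planted clusters are significant in both directions (A/B swap)", {
  world <- make_planted_corpus(synthetic_config(n_genes = 200, n_modules = 4,
                                                seed = 6))
  go_ic <- compute_ic(world$go_corpus, world$go_dag)
  cmpo_ic <- compute_ic(world$cmpo_corpus, world$cmpo_dag)
  # GO-side clusters scored against phenotype ontology
  g <- project_term_graph(world$go_corpus)
  a <- spectral_ncut(g, 4, seed = 1)
  res <- cluster_cross_ontology_similarity(a, world$go_corpus,
                                           world$cmpo_corpus,
                                           world$cmpo_dag, cmpo_ic,
                                           n_rand = 300, seed = 1)
  mods <- vapply(world$go_signature, function(ls)
    as.integer(names(sort(table(a$cluster[ls]), decreasing = TRUE))[1]),
    integer(1))
  expect_true(all(res$p[match(mods, res$cluster)] < 0.05))
  # phenotype-side clusters scored against GO, same code path
  gp <- project_term_graph(world$cmpo_corpus)
  ap <- spectral_ncut(gp, 4, seed = 1)
  resb <- cluster_cross_ontology_similarity(ap, world$cmpo_corpus,
                                            world$go_corpus,
                                            world$go_dag, go_ic,
                                            n_rand = 300, seed = 1)
  modsb <- vapply(world$cmpo_signature, function(ls)
    as.integer(names(sort(table(ap$cluster[ls]), decreasing = TRUE))[1]),
    integer(1))
  expect_true(all(resb$p[match(modsb, resb$cluster)] < 0.05))
})

test_that("term graph writer emits the positive edges", {
  g <- block_graph(3, 3, w_in = 0.8, w_out = 0)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_term_graph(g, path)
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(d), 6)            # 2 * C(3,2) within-block edges
  expect_true(all(d$weight == 0.8))
})
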