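# Shared fixtures and independent brute-force oracles. Oracles are
# deliberately written in the most literal way possible (loops, repeated
# set expansion) so they stay independent of the package's vectorized
# implementations.

# --- fixtures --------------------------------------------------------

# a 3-level chain OBO: leaf is_a mid is_a root, plus an obsolete term
write_chain_obo <- function(path) {
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: T:0000001", "name: root", "",
    "[Term]", "id: T:0000002", "name: mid", "is_a: T:0000001 ! root", "",
    "[Term]", "id: T:0000003", "name: leaf", "is_a: T:0000002", "",
    "[Term]", "id: T:0000004", "name: gone", "is_a: T:0000001",
    "is_obsolete: true", ""), path)
  path
}

# deterministic small annotated world on a random toy DAG
toy_world <- function(seed = 1, n_genes = 8, depth = 3, branching = 2) {
  dag <- make_toy_ontology(depth, branching, seed = seed,
                           extra_edge_prob = 0.2)
  set.seed(seed + 1000)
  leaves <- dag$terms[lengths(dag$children[dag$terms]) == 0]
  direct <- lapply(seq_len(n_genes), function(i)
    sample(dag$terms[-1], sample(1:3, 1)))
  names(direct) <- sprintf("g%02d", seq_len(n_genes))
  corpus <- propagate(direct, dag)
  list(dag = dag, corpus = corpus, ic = compute_ic(corpus, dag),
       leaves = leaves)
}

rand_phenotype_matrix <- function(seed, n_g = 10, n_p = 8, density = 0.4) {
  set.seed(seed)
  repeat {
    m <- matrix(as.numeric(stats::runif(n_g * n_p) < density), n_g, n_p,
                dimnames = list(sprintf("g%02d", 1:n_g),
                                sprintf("P:%03d", 1:n_p)))
    if (all(rowSums(m) > 0)) return(phenotype_matrix(m))
  }
}

# --- oracles ---------------------------------------------------------

# ancestor closure by repeated edge expansion until fixpoint
oracle_ancestors <- function(dag, term) {
  anc <- character(0)
  frontier <- term
  repeat {
    nxt <- unique(unlist(dag$parents[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, anc)
    if (!length(nxt)) break
    anc <- c(anc, nxt)
    frontier <- nxt
  }
  sort(anc)
}

# IC by counting genes whose direct annotations include any
# descendant-or-self of the term
oracle_ic <- function(dag, direct_list, term) {
  desc_or_self <- Filter(function(t) term %in% c(t, oracle_ancestors(dag, t)),
                         dag$terms)
  n <- sum(vapply(direct_list, function(ts)
    any(ts %in% desc_or_self), logical(1)))
  if (n == 0) return(NULL)
  -log(n / length(direct_list))
}

# MICA by full enumeration of common ancestor-or-self sets
oracle_mica <- function(dag, ic, t1, t2) {
  common <- intersect(c(t1, oracle_ancestors(dag, t1)),
                      c(t2, oracle_ancestors(dag, t2)))
  common <- common[common %in% names(ic$ic)]
  vals <- ic$ic[common]
  best <- sort(common[vals == max(vals)])[1]
  list(term = best, ic = unname(ic$ic[best]))
}

# term semantic similarity from first principles
oracle_term_sim <- function(dag, ic, t1, t2, method) {
  a1 <- intersect(c(t1, oracle_ancestors(dag, t1)), names(ic$ic))
  a2 <- intersect(c(t2, oracle_ancestors(dag, t2)), names(ic$ic))
  if (method == "pesquita") {
    num <- sum(ic$ic[intersect(a1, a2)])
    den <- sum(ic$ic[union(a1, a2)])
    return(if (den == 0) 0 else num / den)
  }
  m <- oracle_mica(dag, ic, t1, t2)
  s <- ic$ic[[t1]] + ic$ic[[t2]]
  switch(method,
         resnik = m$ic,
         lin = if (s == 0) 0 else 2 * m$ic / s,
         schlicker = if (s == 0) 0
                     else 2 * m$ic / s * (1 - ic$p[[m$term]]),
         jiang = 1 - min(1, s - 2 * m$ic))
}

# profile similarity from the printed formulas, one pair at a time
oracle_profile_sim <- function(mat, method, i, j) {
  x <- mat[i, ]; y <- mat[j, ]
  n <- length(x)
  switch(method,
    euclidean = 1 / (1 + sum((x - y)^2)),
    hamming = sum(x == y) / n,
    cosine = {
      if (sum(x) == 0 || sum(y) == 0) 0
      else sum(x * y) / (sqrt(sum(x^2)) * sqrt(sum(y^2)))
    },
    jaccard = {
      u <- sum(x == 1 | y == 1)
      if (u == 0) 0 else sum(x == 1 & y == 1) / u
    },
    correlation = {
      if (stats::sd(x) == 0 || stats::sd(y) == 0) 0
      else stats::cor(x, y)
    },
    kappa = {
      p0 <- sum(x == y) / n
      q1 <- mean(x); q2 <- mean(y)
      pc <- q1 * q2 + (1 - q1) * (1 - q2)
      if (abs(1 - pc) < 1e-12) 0 else (p0 - pc) / (1 - pc)
    },
    tfidf = {
      # literal formula: max over all phenotypes of x1 * x2 * IDF(p),
      # so unshared phenotypes contribute 0 to the maximum
      idf <- log(nrow(mat) / (1 + colSums(mat)))
      max(x * y * idf)
    })
}

# AUC by exhaustive double loop with half credit for ties
oracle_auc <- function(pos_scores, neg_scores) {
  wins <- 0
  for (p in pos_scores) for (q in neg_scores)
    wins <- wins + (p > q) + 0.5 * (p == q)
  wins / (length(pos_scores) * length(neg_scores))
}

# BH step-up from the direct formula q_(i) = min_{j >= i} p_(j) m / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    q[o[i]] <- min(pmin(1, p[o[js]] * m / js))
  }
  q
}

# normalized cut by definition
oracle_ncut <- function(w, cl) {
  tot <- 0
  for (k in unique(cl)) {
    inC <- cl == k
    vol <- sum(w[inC, , drop = FALSE])
    if (vol > 0) tot <- tot + sum(w[inC, !inC, drop = FALSE]) / vol
  }
  tot
}

# minimum 2-way normalized cut by exhaustive enumeration (n <= 12);
# node 1 is fixed to cluster 1 to halve the search space
oracle_min_ncut2 <- function(w) {
  n <- nrow(w)
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    cl <- c(1L, 1L + as.integer(intToBits(code))[seq_len(n - 1)])
    best <- min(best, oracle_ncut(w, cl))
  }
  best
}
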