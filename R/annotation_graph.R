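# Annotation-driven definition of functions/phenotypes: bipartite
# projection of gene-term annotations into a weighted term graph,
# normalized-cut spectral clustering with recursive splitting, and
# cross-ontology cluster-coherence tests with randomization nulls.

#' Project an annotation corpus onto a weighted term graph
#'
#' Links two terms if they share at least one annotated gene; the edge
#' weight is the Jaccard index of the terms' (ancestor-propagated) gene
#' sets, `|genes(t1) & genes(t2)| / |genes(t1) | genes(t2)|`, which
#' compensates for high-level terms inheriting genes from their
#' children. Terms with no annotated gene are dropped with a warning.
#'
#' @param corpus an `annotation_corpus`.
#' @param term_set terms to include (default: all terms with at least
#'   one propagated gene).
#' @return object of class `term_graph` with elements `nodes` and `w`
#'   (symmetric weight matrix, zero diagonal).
#' @export
project_term_graph <- function(corpus, term_set = NULL) {
  genes <- corpus$universe
  all_terms <- unique(unlist(corpus$propagated, use.names = FALSE))
  if (is.null(term_set)) term_set <- sort(all_terms)
  missing_terms <- setdiff(term_set, all_terms)
  if (length(missing_terms)) {
    warning(length(missing_terms), " term(s) with no annotated gene dropped")
    term_set <- setdiff(term_set, missing_terms)
  }
  if (!length(term_set)) stop("no annotated terms to project")
  # term x gene incidence
  M <- matrix(0, length(term_set), length(genes),
              dimnames = list(term_set, genes))
  for (g in genes) {
    ts <- intersect(corpus$propagated[[g]], term_set)
    M[ts, g] <- 1
  }
  inter <- tcrossprod(M)
  sz <- rowSums(M)
  uni <- outer(sz, sz, "+") - inter
  w <- inter / uni
  w[inter == 0] <- 0
  diag(w) <- 0
  structure(list(nodes = term_set, w = w), class = "term_graph")
}

#' @export
print.term_graph <- function(x, ...) {
  cat("Term graph:", length(x$nodes), "nodes,",
      sum(x$w[upper.tri(x$w)] > 0), "edges\n")
  invisible(x)
}

#' Write a term graph as a weighted edge-list TSV
#'
#' @param graph a `term_graph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_term_graph <- function(graph, path) {
  up <- upper_pairs(length(graph$nodes))
  w <- graph$w[up]
  keep <- w > 0
  utils::write.table(
    data.frame(term1 = graph$nodes[up[keep, 1]],
               term2 = graph$nodes[up[keep, 2]],
               weight = w[keep]),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# connected components of a weight matrix by BFS; returns integer labels
graph_components <- function(w) {
  n <- nrow(w)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(w[v, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Normalized-cut value of a partition
#'
#' `sum_C cut(C, V \ C) / vol(C)` over clusters `C`; clusters with zero
#' volume (isolated nodes) contribute 0.
#'
#' @param w symmetric weight matrix.
#' @param clusters integer cluster labels, one per node.
#' @return the normalized-cut objective value.
#' @export
ncut_value <- function(w, clusters) {
  total <- 0
  for (cl in unique(clusters)) {
    inC <- clusters == cl
    vol <- sum(w[inC, , drop = FALSE])
    if (vol == 0) next
    cut <- sum(w[inC, !inC, drop = FALSE])
    total <- total + cut / vol
  }
  total
}

# spectral embedding + k-means on one connected weight matrix
spectral_kmeans <- function(w, k, nstart = 25) {
  n <- nrow(w)
  if (k >= n) return(seq_len(n))
  d <- rowSums(w)
  d[d == 0] <- 1
  dis <- 1 / sqrt(d)
  L <- dis * w * rep(dis, each = n)  # D^-1/2 W D^-1/2
  ev <- eigen((L + t(L)) / 2, symmetric = TRUE)
  U <- ev$vectors[, seq_len(k), drop = FALSE]
  nrm <- sqrt(rowSums(U^2))
  nrm[nrm == 0] <- 1
  U <- U / nrm
  if (k == 1) return(rep(1L, n))
  km <- stats::kmeans(U, centers = k, nstart = nstart, iter.max = 100)
  km$cluster
}

#' Normalized-cut spectral clustering of a term graph
#'
#' Standard relaxation of the normalized-cut objective: symmetric
#' normalized Laplacian, embedding in the k leading eigenvectors with
#' row renormalization, seeded k-means with multiple restarts.
#' Disconnected graphs are handled by assigning connected components
#' first (a partition that never splits a component has zero cut): when
#' there are at least `k` components, components are grouped into `k`
#' clusters; otherwise `k` is apportioned across components by size and
#' each component is clustered separately.
#'
#' @param graph a `term_graph`.
#' @param k number of clusters.
#' @param seed integer seed (k-means restarts).
#' @param nstart k-means restarts (default 25).
#' @return object of class `cluster_assignment`: list with `cluster`
#'   (named integer vector over nodes, contiguous ids), `k`, `objective`
#'   (normalized-cut value), `seed`.
#' @export
spectral_ncut <- function(graph, k, seed = 1L, nstart = 25) {
  w <- graph$w
  n <- nrow(w)
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop("k exceeds the number of nodes")
  assign <- integer(n)
  if (k == 1) {
    assign[] <- 1L
  } else {
    comp <- graph_components(w)
    nc <- max(comp)
    if (nc >= k) {
      # group whole components into k clusters: biggest k-1 components
      # stay alone, the rest pool into one (objective is 0 either way)
      sizes <- tabulate(comp)
      ord <- order(sizes, decreasing = TRUE)
      lab <- integer(nc)
      lab[ord[seq_len(k - 1)]] <- seq_len(k - 1)
      lab[lab == 0L] <- k
      assign <- lab[comp]
    } else {
      # apportion k across components by size (each gets >= 1)
      sizes <- tabulate(comp)
      alloc <- pmax(1L, floor(k * sizes / sum(sizes)))
      alloc <- pmin(alloc, sizes)
      while (sum(alloc) < k) {
        i <- which.max(sizes - alloc)
        alloc[i] <- alloc[i] + 1L
      }
      while (sum(alloc) > k) {
        i <- which(alloc > 1L)[which.max(alloc[alloc > 1L] / sizes[alloc > 1L])]
        alloc[i] <- alloc[i] - 1L
      }
      off <- 0L
      with_seed(seed, for (c_i in seq_len(nc)) {
        idx <- which(comp == c_i)
        sub <- spectral_kmeans(w[idx, idx, drop = FALSE], alloc[c_i],
                               nstart = nstart)
        assign[idx] <- sub + off
        off <- off + max(sub)
      })
    }
  }
  # contiguous ids in order of first appearance
  assign <- match(assign, unique(assign))
  names(assign) <- graph$nodes
  structure(list(cluster = assign, k = max(assign),
                 objective = ncut_value(w, assign), seed = seed),
            class = "cluster_assignment")
}

#' Cluster a graph, then re-cluster selected clusters
#'
#' First partitions the graph into `base_k` clusters, then re-clusters
#' each targeted cluster's induced subgraph. Targets are addressed by
#' size rank (1 = largest, ties by lower cluster id). The study's GO
#' plan is base 100 with the largest cluster split into 33 and the
#' second largest into 9, giving 100 - 2 + 33 + 9 = 140 clusters; the
#' phenotype ontology uses a flat k = 13.
#'
#' @param graph a `term_graph`.
#' @param base_k initial number of clusters.
#' @param splits list of `c(rank, sub_k)` pairs.
#' @param seed integer seed.
#' @param nstart k-means restarts.
#' @return a `cluster_assignment`; total clusters
#'   `base_k - length(splits) + sum(sub_k)`.
#' @export
recursive_split <- function(graph, base_k, splits = list(), seed = 1L,
                            nstart = 25) {
  base <- spectral_ncut(graph, base_k, seed = seed, nstart = nstart)
  assign <- base$cluster
  if (length(splits)) {
    sizes <- table(assign)
    rank_ids <- as.integer(names(sort(sizes, decreasing = TRUE)))
    next_id <- max(assign)
    for (sp in splits) {
      rank <- sp[[1]]; sub_k <- sp[[2]]
      if (rank > length(rank_ids)) stop("split rank out of range")
      target <- rank_ids[[rank]]
      idx <- which(assign == target)
      if (length(idx) < sub_k)
        stop("split target (", length(idx), " nodes) smaller than sub_k=",
             sub_k)
      sub_graph <- structure(list(nodes = graph$nodes[idx],
                                  w = graph$w[idx, idx, drop = FALSE]),
                             class = "term_graph")
      sub <- spectral_ncut(sub_graph, sub_k, seed = seed + rank,
                           nstart = nstart)
      assign[idx] <- next_id + sub$cluster
      next_id <- next_id + sub_k
    }
  }
  assign <- match(assign, unique(assign))
  names(assign) <- graph$nodes
  structure(list(cluster = assign, k = max(assign),
                 objective = ncut_value(graph$w, assign), seed = seed),
            class = "cluster_assignment")
}

# mean similarity over distinct term pairs of a set, using a
# precomputed term similarity matrix; NA if < 2 terms. `counts` (genes
# per term) switches to the gene-frequency-weighted mean with pair
# weight n(b1) * n(b2).
mean_term_set_sim <- function(TS, terms, counts = NULL) {
  keep <- terms %in% rownames(TS)
  terms <- terms[keep]
  if (length(terms) < 2) return(NA_real_)
  s <- TS[terms, terms]
  ut <- upper.tri(s)
  if (is.null(counts)) return(mean(s[ut]))
  counts <- counts[keep]
  w <- outer(counts, counts)[ut]
  sum(w * s[ut]) / sum(w)
}

#' Cross-ontology coherence of term clusters
#'
#' For each cluster of ontology-A terms: collects the genes annotated
#' (propagated) to any cluster term, takes those genes' direct
#' ontology-B terms, and computes the mean ontology-B semantic
#' similarity (default Resnik) over all distinct unordered B-term pairs.
#' The null redistributes A-terms over clusters by shuffling the
#' term-to-cluster assignment while preserving cluster sizes, and
#' recomputes the statistic. Clusters linked to fewer than two B-terms
#' are excluded rather than scored. Empirical p-values use the +1
#' correction; q-values are BH across scored clusters; significance at
#' `q <= alpha`.
#'
#' @param assign a `cluster_assignment` over ontology-A terms.
#' @param corpus_a ontology-A `annotation_corpus` (gene sets via
#'   propagated annotations).
#' @param corpus_b ontology-B `annotation_corpus` (linked terms via
#'   direct annotations).
#' @param dag_b,ic_b ontology-B DAG and IC.
#' @param method term similarity method for ontology B (default
#'   `"resnik"`).
#' @param n_rand number of randomizations (default 100).
#' @param seed integer seed.
#' @param alpha FDR threshold (default 0.01).
#' @param gene_link how cluster terms collect genes: `"propagated"`
#'   (default) inherits genes of descendant terms, so a cluster
#'   containing a high-level foreign term links that term's whole
#'   subtree of genes (which correctly penalizes incoherent term sets);
#'   `"direct"` uses only genes directly annotated to a cluster term.
#' @param weighting `"gene_frequency"` (default) weights each B-term
#'   pair by the product of the numbers of cluster genes carrying the
#'   two terms, so terms carried by a single noisy gene barely count;
#'   `"unweighted"` averages over distinct B-term pairs equally.
#' @param max_coverage A-terms whose propagated gene set covers more
#'   than this fraction of the universe (default 0.5; the root in the
#'   extreme) are treated as uninformative and contribute no gene
#'   linkage, in observed and null statistics alike.
#' @return data frame with columns `cluster`, `size`, `n_linked_terms`,
#'   `observed`, `p`, `q`, `significant`, `excluded`.
#' @export
cluster_cross_ontology_similarity <- function(assign, corpus_a, corpus_b,
                                              dag_b, ic_b,
                                              method = "resnik",
                                              n_rand = 100, seed = 1L,
                                              alpha = 0.01,
                                              gene_link = c("propagated",
                                                            "direct"),
                                              weighting = c("gene_frequency",
                                                            "unweighted"),
                                              max_coverage = 0.5) {
  gene_link <- match.arg(gene_link)
  weighting <- match.arg(weighting)
  terms_a <- names(assign$cluster)
  ann <- if (gene_link == "direct") corpus_a$direct else corpus_a$propagated
  genes_of_term <- lapply(terms_a, function(t)
    corpus_a$universe[vapply(ann, function(ts) t %in% ts, logical(1))])
  names(genes_of_term) <- terms_a
  coverage <- lengths(genes_of_term) / length(corpus_a$universe)
  genes_of_term[coverage > max_coverage] <-
    replicate(sum(coverage > max_coverage), character(0), simplify = FALSE)
  # direct B-terms per gene
  b_terms_of_gene <- corpus_b$direct
  # per-term counts of linked ontology-B terms over a cluster's genes
  linked_b <- function(term_subset) {
    g <- unique(unlist(genes_of_term[term_subset], use.names = FALSE))
    table(unlist(b_terms_of_gene[intersect(g, names(b_terms_of_gene))],
                 use.names = FALSE))
  }
  all_b <- sort(intersect(unique(unlist(b_terms_of_gene, use.names = FALSE)),
                          names(ic_b$ic)))
  TS <- term_similarity_matrix(all_b, all_b, method, dag_b, ic_b)
  stat <- function(tab) {
    cnt <- if (weighting == "gene_frequency") as.numeric(tab) else NULL
    mean_term_set_sim(TS, names(tab), cnt)
  }

  ids <- sort(unique(assign$cluster))
  members <- lapply(ids, function(cl) terms_a[assign$cluster == cl])
  obs_tabs <- lapply(members, linked_b)
  observed <- vapply(obs_tabs, stat, numeric(1))
  n_linked <- vapply(obs_tabs, function(tab)
    sum(names(tab) %in% all_b), integer(1))

  null <- matrix(NA_real_, length(ids), n_rand)
  with_seed(seed, for (b in seq_len(n_rand)) {
    # permute which term carries which label: cluster sizes preserved
    perm <- sample(terms_a)
    for (i in seq_along(ids)) {
      ts <- perm[assign$cluster == ids[i]]
      null[i, b] <- stat(linked_b(ts))
    }
  })
  p <- vapply(seq_along(ids), function(i) {
    if (is.na(observed[i])) return(NA_real_)
    nv <- null[i, !is.na(null[i, ])]
    (sum(nv >= observed[i]) + 1) / (length(nv) + 1)
  }, numeric(1))
  q <- rep(NA_real_, length(p))
  tested <- !is.na(p)
  q[tested] <- stats::p.adjust(p[tested], method = "BH")
  data.frame(cluster = ids,
             size = lengths(members),
             n_linked_terms = n_linked,
             observed = observed, p = p, q = q,
             significant = !is.na(q) & q <= alpha,
             excluded = is.na(observed))
}

#' Write a cluster assignment TSV
#'
#' @param assign a `cluster_assignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cluster_assignment <- function(assign, path) {
  utils::write.table(
    data.frame(term = names(assign$cluster),
               cluster = unname(assign$cluster)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
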