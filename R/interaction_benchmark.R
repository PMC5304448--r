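# Benchmarking phenotypic similarity measures against protein
# interactions: ROC AUC over positive/negative pairs, nearest-neighbour
# interaction recovery with hypergeometric significance, and the
# inter-measure correlation dendrogram.

#' Construct a labelled interaction pair set
#'
#' Unordered gene pairs labelled positive (physical/curated interactions)
#' or negative (curated non-interactions). Self pairs are rejected and
#' pairs are canonicalized so that overlap between the two sets is
#' detected regardless of gene order. Pairs with genes outside
#' `universe` are dropped (the evaluation universe is the screened gene
#' set).
#'
#' @param positives,negatives 2-column character matrices/data frames.
#' @param universe gene ids considered.
#' @return object of class `interaction_set` with elements `positives`,
#'   `negatives` (2-column matrices), `universe`.
#' @export
interaction_set <- function(positives, negatives, universe) {
  canon <- function(p) {
    p <- as.matrix(p)[, 1:2, drop = FALSE]
    storage.mode(p) <- "character"
    if (any(p[, 1] == p[, 2])) stop("self-pairs not allowed")
    keep <- p[, 1] %in% universe & p[, 2] %in% universe
    p <- p[keep, , drop = FALSE]
    p <- cbind(pmin(p[, 1], p[, 2]), pmax(p[, 1], p[, 2]))
    p[!duplicated(paste(p[, 1], p[, 2])), , drop = FALSE]
  }
  pos <- canon(positives)
  neg <- canon(negatives)
  overlap <- intersect(paste(pos[, 1], pos[, 2]),
                       paste(neg[, 1], neg[, 2]))
  if (length(overlap))
    stop(length(overlap), " pair(s) labelled both positive and negative")
  structure(list(positives = pos, negatives = neg,
                 universe = as.character(universe)),
            class = "interaction_set")
}

#' Read / write interaction pair TSVs
#'
#' Dialect: `gene1<TAB>gene2<TAB>label(pos|neg)<TAB>source`.
#'
#' @param path file path.
#' @param universe gene universe for [interaction_set()].
#' @return an `interaction_set`.
#' @export
read_interactions <- function(path, universe) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(d) < 3) stop("need columns gene1, gene2, label")
  interaction_set(d[d[[3]] == "pos", 1:2], d[d[[3]] == "neg", 1:2],
                  universe)
}

#' @rdname read_interactions
#' @param iset an `interaction_set`.
#' @param source source tag written to column 4.
#' @export
write_interactions <- function(iset, path, source = "synthetic") {
  d <- rbind(data.frame(g1 = iset$positives[, 1], g2 = iset$positives[, 2],
                        label = "pos", source = source),
             data.frame(g1 = iset$negatives[, 1], g2 = iset$negatives[, 2],
                        label = "neg", source = source))
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

sim_lookup <- function(sim, pairs) {
  i <- match(pairs[, 1], rownames(sim))
  j <- match(pairs[, 2], colnames(sim))
  if (anyNA(i) || anyNA(j))
    stop("interaction pair gene(s) missing from similarity matrix")
  sim[cbind(i, j)]
}

#' ROC AUC of a similarity measure against interaction labels
#'
#' The probability that a positive (interacting) pair receives a higher
#' similarity than a negative pair, with ties counted 1/2 (Mann-Whitney
#' convention, computed via the rank identity). Binary-profile measures
#' produce massive ties, so the tie convention matters.
#'
#' @param sim symmetric gene similarity matrix with dimnames.
#' @param iset an `interaction_set`; every pair must be scored in `sim`.
#' @return AUC in \[0, 1\].
#' @export
auc_interactions <- function(sim, iset) {
  if (!nrow(iset$positives) || !nrow(iset$negatives))
    stop("need at least one positive and one negative pair")
  sp <- sim_lookup(sim, iset$positives)
  sn <- sim_lookup(sim, iset$negatives)
  r <- rank(c(sp, sn))  # mean ranks on ties => 1/2 tie credit
  (sum(r[seq_along(sp)]) - length(sp) * (length(sp) + 1) / 2) /
    (length(sp) * length(sn))
}

#' Nearest-neighbour interaction recovery score
#'
#' For each gene, finds its most similar partner (ties broken uniformly
#' at random, seeded) and counts the genes whose chosen partner forms a
#' known interacting pair.
#'
#' @param sim symmetric gene similarity matrix with dimnames.
#' @param known_pairs 2-column matrix/data frame of known interacting
#'   gene pairs.
#' @param seed integer seed for tie breaking.
#' @return list with `x` (the count), and `details`: data frame of gene,
#'   chosen partner, hit flag.
#' @export
nearest_neighbor_score <- function(sim, known_pairs, seed = 1L) {
  genes <- rownames(sim)
  if (length(genes) < 2) stop("need at least two genes")
  kp <- as.matrix(known_pairs)
  keys <- if (nrow(kp)) pair_key(kp[, 1], kp[, 2]) else character(0)
  partner <- with_seed(seed, vapply(seq_along(genes), function(i) {
    s <- sim[i, ]
    s[i] <- -Inf
    top <- which(s == max(s))
    genes[if (length(top) == 1) top else sample(top, 1)]
  }, character(1)))
  hit <- pair_key(genes, partner) %in% keys
  list(x = sum(hit),
       details = data.frame(gene = genes, partner = partner, hit = hit,
                            stringsAsFactors = FALSE))
}

#' Hypergeometric tail probability for the nearest-neighbour score
#'
#' P(X >= x) for X hypergeometric with population `N` (all possible
#' gene pairs), `K` successes (known interactions) and `n` draws (one
#' nearest-neighbour pair per gene), i.e. `1 - phyper(x - 1, K, N - K, n)`.
#' The study's full-data parameterization is N = 4198*4197/2 pairs,
#' K = 29649 known interactions, n = 4198 draws.
#'
#' @param x observed hit count.
#' @param K number of known interacting pairs in the population.
#' @param N total number of possible pairs.
#' @param n number of draws.
#' @return tail probability in (0, 1\].
#' @export
hypergeometric_pvalue <- function(x, K, N, n) {
  if (x < 0 || x > n || n > N || K > N || K < 0)
    stop("invalid hypergeometric parameters")
  stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
}

#' Average-linkage dendrogram over similarity measures
#'
#' Vectorizes each measure's upper-triangle pairwise scores, computes
#' Pearson correlation between measures, and clusters measures by
#' average linkage (UPGMA) on the distance 1 - PCC. Measures with a
#' constant score vector have undefined correlation and are dropped with
#' a warning.
#'
#' @param sims named list of similarity matrices over the same genes.
#' @return an [stats::hclust] object over the measure names.
#' @export
measure_correlation_dendrogram <- function(sims) {
  if (length(sims) < 2) stop("need at least two measures")
  genes <- rownames(sims[[1]])
  up <- upper_pairs(length(genes))
  vecs <- vapply(sims, function(s) {
    s <- s[genes, genes]
    s[up]
  }, numeric(nrow(up)))
  sds <- apply(vecs, 2, stats::sd)
  if (any(sds == 0)) {
    warning("constant measure(s) dropped: ",
            paste(colnames(vecs)[sds == 0], collapse = ", "))
    vecs <- vecs[, sds > 0, drop = FALSE]
  }
  if (ncol(vecs) < 2) stop("fewer than two non-constant measures")
  d <- stats::as.dist(1 - stats::cor(vecs))
  stats::hclust(d, method = "average")
}
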