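# Do phenotypes indicate function? Per-phenotype mean GO similarity with
# permutation nulls and BH correction, cross-ontology similarity binning,
# the high-similarity randomization check, and IC-distribution
# comparison between a gene subset and the full corpus.

#' Mean functional similarity among genes sharing each phenotype
#'
#' For each phenotype column, averages the gene-pair functional (GO)
#' similarity over all unordered pairs of genes showing the phenotype.
#' Genes absent from `go_sim` (no functional annotation) are excluded;
#' phenotypes with fewer than two annotated genes are reported as
#' excluded with `NA` mean.
#'
#' @param mat a [phenotype_matrix()].
#' @param go_sim symmetric gene-pair functional similarity matrix with
#'   gene dimnames (e.g. from [gene_similarity_matrix()]).
#' @return data frame with columns `phenotype`, `n_genes` (annotated
#'   genes showing it), `mean_sim`, `excluded`.
#' @export
per_phenotype_mean_go_similarity <- function(mat, go_sim) {
  genes <- intersect(rownames(mat), rownames(go_sim))
  m <- unclass(mat)[genes, , drop = FALSE]
  res <- lapply(colnames(m), function(p) {
    g <- genes[m[, p] == 1]
    if (length(g) < 2)
      return(data.frame(phenotype = p, n_genes = length(g),
                        mean_sim = NA_real_, excluded = TRUE))
    s <- go_sim[g, g]
    data.frame(phenotype = p, n_genes = length(g),
               mean_sim = mean(s[upper.tri(s)]), excluded = FALSE)
  })
  do.call(rbind, res)
}

# mean similarity among a gene set, NA if < 2 genes
mean_pair_sim <- function(go_sim, g) {
  if (length(g) < 2) return(NA_real_)
  s <- go_sim[g, g]
  mean(s[upper.tri(s)])
}

#' Per-phenotype functional-coherence permutation test
#'
#' Tests, for each phenotype, whether genes sharing it are functionally
#' more similar (mean GO gene-pair similarity) than expected by chance.
#' Each permutation reassigns the phenotype's gene links to a uniform
#' random subset of the matrix genes of the same size, so column sums
#' are preserved exactly (row sums are not). Empirical p-values use the
#' +1/(n+1) correction and are BH-adjusted across tested phenotypes;
#' significance is declared at `q <= alpha` (default 0.01, the study's
#' FDR operating point).
#'
#' @param mat a [phenotype_matrix()].
#' @param go_sim symmetric gene-pair functional similarity matrix.
#' @param n_perm number of permutations (default 100).
#' @param seed integer seed.
#' @param alpha FDR significance threshold (default 0.01).
#' @param ic_cmpo optional `term_ic` over the phenotype ontology, used to
#'   attach each phenotype's IC for specificity ordering.
#' @return data frame with columns `phenotype`, `n_genes`, `observed`,
#'   `p`, `q`, `significant`, `ic_cmpo`, `excluded`; attribute `null`
#'   holds the matrix of permuted means (phenotypes x permutations).
#' @export
permutation_test <- function(mat, go_sim, n_perm = 100, seed = 1L,
                             alpha = 0.01, ic_cmpo = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  obs <- per_phenotype_mean_go_similarity(mat, go_sim)
  all_genes <- rownames(mat)
  annotated <- intersect(all_genes, rownames(go_sim))
  col_sums <- colSums(unclass(mat))
  null <- matrix(NA_real_, nrow(obs), n_perm,
                 dimnames = list(obs$phenotype, NULL))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      for (i in seq_len(nrow(obs))) {
        if (obs$excluded[i]) next
        g <- sample(all_genes, col_sums[[obs$phenotype[i]]])
        null[i, b] <- mean_pair_sim(go_sim, intersect(g, annotated))
      }
    }
  })
  p <- vapply(seq_len(nrow(obs)), function(i) {
    if (obs$excluded[i]) return(NA_real_)
    nv <- null[i, !is.na(null[i, ])]
    (sum(nv >= obs$mean_sim[i]) + 1) / (length(nv) + 1)
  }, numeric(1))
  q <- rep(NA_real_, length(p))
  tested <- !is.na(p)
  q[tested] <- stats::p.adjust(p[tested], method = "BH")
  out <- data.frame(phenotype = obs$phenotype, n_genes = obs$n_genes,
                    observed = obs$mean_sim, p = p, q = q,
                    significant = !is.na(q) & q <= alpha,
                    ic_cmpo = if (is.null(ic_cmpo)) NA_real_
                              else unname(ic_cmpo$ic[obs$phenotype]),
                    excluded = obs$excluded)
  attr(out, "null") <- null
  out
}

#' Quartile summary of one similarity within bins of another
#'
#' Assigns gene pairs to bins of `sim_a` and summarizes the
#' distribution of `sim_b` within each bin (n, quartiles), mirroring
#' box-plot views of functional versus phenotypic similarity. Run twice
#' with arguments swapped for the two directions.
#'
#' @param sim_a,sim_b numeric vectors of scores over the same pair
#'   universe (e.g. upper triangles of two similarity matrices).
#' @param breaks bin breaks for `sim_a`; default deciles (duplicate
#'   quantiles collapsed).
#' @return data frame with columns `bin`, `lower`, `upper`, `n`, `q1`,
#'   `median`, `q3`.
#' @export
cross_similarity_bins <- function(sim_a, sim_b, breaks = NULL) {
  if (length(sim_a) != length(sim_b))
    stop("score vectors must cover the same pair universe")
  if (is.null(breaks)) {
    breaks <- unique(stats::quantile(sim_a, probs = seq(0, 1, 0.1)))
    if (length(breaks) < 2) breaks <- range(sim_a) + c(-1e-9, 1e-9)
  }
  bin <- cut(sim_a, breaks = breaks, include.lowest = TRUE)
  res <- lapply(levels(bin), function(lv) {
    v <- sim_b[!is.na(bin) & bin == lv]
    qs <- if (length(v)) stats::quantile(v, c(0.25, 0.5, 0.75))
          else rep(NA_real_, 3)
    data.frame(bin = lv, n = length(v),
               q1 = qs[[1]], median = qs[[2]], q3 = qs[[3]])
  })
  out <- do.call(rbind, res)
  bounds <- cbind(breaks[-length(breaks)], breaks[-1])
  out$lower <- bounds[, 1]
  out$upper <- bounds[, 2]
  out[, c("bin", "lower", "upper", "n", "q1", "median", "q3")]
}

#' Randomization check for high-phenotypic-similarity pairs
#'
#' Tests whether pairs with phenotypic similarity at or above a
#' threshold have higher mean functional similarity than the same
#' number of pairs drawn at random (without replacement) from all
#' pairs.
#'
#' @param sim_a phenotypic similarity scores (vector over pairs).
#' @param sim_b functional similarity scores over the same pairs.
#' @param threshold selection threshold on `sim_a`.
#' @param n_rand number of randomizations (default 100).
#' @param seed integer seed.
#' @return list with `observed`, `null` (vector of randomized means),
#'   `p` (empirical, +1 corrected), `n_selected`.
#' @export
high_similarity_randomization <- function(sim_a, sim_b, threshold,
                                          n_rand = 100, seed = 1L) {
  if (threshold > max(sim_a)) stop("threshold above maximum similarity")
  sel <- sim_a >= threshold
  observed <- mean(sim_b[sel])
  k <- sum(sel)
  null <- with_seed(seed, vapply(seq_len(n_rand), function(b)
    mean(sample(sim_b, k)), numeric(1)))
  list(observed = observed, null = null,
       p = (sum(null >= observed) + 1) / (n_rand + 1),
       n_selected = k)
}

#' IC distribution of annotations: gene subset versus full corpus
#'
#' For a gene subset and for the whole corpus, bins the IC values of all
#' direct gene-term annotations and returns the per-bin proportions
#' (each curve sums to 1). Used to check that genes with phenotypes are
#' not a biased sample of the functional annotation space.
#'
#' @param corpus an `annotation_corpus`.
#' @param subset character vector of genes (subset of the universe).
#' @param ic a `term_ic`.
#' @param bins number of equal-width IC bins (default 10) or a vector of
#'   breaks.
#' @return data frame with columns `lower`, `upper`, `prop_subset`,
#'   `prop_all`.
#' @export
ic_profile_comparison <- function(corpus, subset, ic, bins = 10) {
  if (!length(subset)) stop("empty gene subset")
  if (!all(subset %in% corpus$universe))
    stop("subset contains genes outside the corpus universe")
  ann_ic <- function(genes) {
    v <- unlist(lapply(corpus$direct[genes], function(ts)
      ic$ic[intersect(ts, names(ic$ic))]), use.names = FALSE)
    v
  }
  all_v <- ann_ic(corpus$universe)
  sub_v <- ann_ic(subset)
  if (length(bins) == 1) {
    rng <- range(all_v)
    breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  } else breaks <- bins
  h <- function(v) {
    ct <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE,
                                all.inside = TRUE),
                   nbins = length(breaks) - 1)
    ct / sum(ct)
  }
  data.frame(lower = breaks[-length(breaks)], upper = breaks[-1],
             prop_subset = h(sub_v), prop_all = h(all_v))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over [stats::p.adjust()] kept as the package's single
#' multiple-testing entry point.
#'
#' @param p numeric vector of p-values.
#' @return BH-adjusted q-values.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
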