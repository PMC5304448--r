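# Ontology semantic similarity between terms (Resnik, Lin, Schlicker,
# Jiang-Conrath, Pesquita/simGIC) and its aggregation to gene pairs over
# annotation sets.

#' Semantic similarity between two ontology terms
#'
#' With `t_MICA` the most informative common ancestor (see [mica()]):
#' \describe{
#'   \item{resnik}{\eqn{IC(t_{MICA})}}
#'   \item{lin}{\eqn{2 IC(t_{MICA}) / (IC(t_1) + IC(t_2))}}
#'   \item{schlicker}{Lin's value times \eqn{1 - p(t_{MICA})} (relevance
#'     weighting that down-ranks shallow ancestors)}
#'   \item{jiang}{\eqn{1 - \min(1, IC(t_1) + IC(t_2) - 2 IC(t_{MICA}))},
#'     the bounded Jiang-Conrath similarity}
#'   \item{pesquita}{simGIC: summed IC of common ancestors-or-self over
#'     summed IC of the union of ancestors-or-self}
#' }
#' Lin and Schlicker are defined as 0 (with a warning) when
#' \eqn{IC(t_1) + IC(t_2) = 0} (both terms at the root).
#'
#' @param t1,t2 term identifiers present in `ic`'s domain.
#' @param method one of `"resnik"`, `"lin"`, `"schlicker"`, `"jiang"`,
#'   `"pesquita"`.
#' @param dag an [onto_dag()].
#' @param ic a `term_ic` from [compute_ic()].
#' @return a single numeric similarity value.
#' @export
term_similarity <- function(t1, t2,
                            method = c("resnik", "lin", "schlicker",
                                       "jiang", "pesquita"),
                            dag, ic) {
  method <- match.arg(method)
  term_similarity_matrix(t1, t2, method, dag, ic)[1, 1]
}

#' All-pairs term similarity matrix
#'
#' Vectorized computation over the ancestor-or-self indicator matrix;
#' the single-pair [term_similarity()] delegates here.
#'
#' @param terms1,terms2 character vectors of term ids.
#' @inheritParams term_similarity
#' @return numeric matrix of dimension `length(terms1)` x `length(terms2)`.
#' @export
term_similarity_matrix <- function(terms1, terms2,
                                   method = c("resnik", "lin", "schlicker",
                                              "jiang", "pesquita"),
                                   dag, ic) {
  method <- match.arg(method)
  dom <- names(ic$ic)
  U <- unique(c(terms1, terms2))
  miss <- setdiff(U, dom)
  if (length(miss))
    stop("term(s) without defined IC, e.g. '", miss[[1]], "'")
  A <- matrix(FALSE, length(U), length(dom), dimnames = list(U, dom))
  for (t in U) A[t, intersect(term_ancestors(dag, t), dom)] <- TRUE
  icv <- ic$ic[dom]
  i1 <- match(terms1, U)
  i2 <- match(terms2, U)

  if (method == "pesquita") {
    Aw <- A * rep(icv, each = nrow(A))
    common <- tcrossprod(Aw, A)           # summed IC of shared ancestors
    self <- rowSums(Aw)
    uni <- outer(self, self, "+") - common
    bad <- uni == 0
    if (any(bad[i1, i2, drop = FALSE]))
      warning("all ancestors have IC 0: pesquita set to 0")
    uni[bad] <- 1
    out <- (common / uni)
    out[bad] <- 0
    return(structure(out[i1, i2, drop = FALSE],
                     dimnames = list(terms1, terms2)))
  }

  # progressive fill in decreasing-IC order (ties: lowest term id)
  # gives IC and p of the most informative common ancestor per pair
  ord <- order(-icv, dom)
  n <- length(U)
  icm <- matrix(NA_real_, n, n)
  pm <- matrix(NA_real_, n, n)
  for (t in ord) {
    d <- A[, t]
    if (!any(d)) next
    unset <- which(outer(d, d) & is.na(icm))
    if (length(unset)) {
      icm[unset] <- icv[[t]]
      pm[unset] <- ic$p[[t]]
    }
    if (!anyNA(icm)) break
  }
  if (anyNA(icm[i1, i2]))
    stop("term pair(s) with no common ancestor with defined IC")
  self_ic <- vapply(U, function(t) ic$ic[[t]], numeric(1))
  icsum <- outer(self_ic, self_ic, "+")
  out <- switch(method,
    resnik = icm,
    lin = ,
    schlicker = {
      bad <- icsum == 0
      if (any(bad[i1, i2, drop = FALSE]))
        warning("IC(t1)+IC(t2)=0: ", method, " set to 0")
      denom <- ifelse(bad, 1, icsum)
      v <- 2 * icm / denom
      if (method == "schlicker") v <- v * (1 - pm)
      v[bad] <- 0
      v
    },
    jiang = {
      dist <- icsum - 2 * icm
      dist[dist > 1] <- 1
      1 - dist
    })
  structure(out[i1, i2, drop = FALSE], dimnames = list(terms1, terms2))
}

aggregate_term_matrix <- function(S, aggregation) {
  switch(aggregation,
    max = max(S),
    average = mean(S),
    bma = {
      row_max <- S[cbind(seq_len(nrow(S)), max.col(S, "first"))]
      tS <- t(S)
      col_max <- tS[cbind(seq_len(nrow(tS)), max.col(tS, "first"))]
      (mean(row_max) + mean(col_max)) / 2
    })
}

#' Gene-pair semantic similarity
#'
#' Scores a gene pair by aggregating the term-pair similarity matrix
#' between the genes' direct annotation sets (propagation enters only
#' through ancestor search and IC, so pairs do not trivially share the
#' root in simGIC's denominator). Aggregations: `max` over all term
#' pairs, `average` over all term pairs, or `bma` (best-match average:
#' the mean of averaged row maxima and averaged column maxima, symmetric
#' by construction).
#'
#' @param g1,g2 gene identifiers present in `corpus$universe`.
#' @param corpus an `annotation_corpus`.
#' @param method term similarity method, see [term_similarity()].
#' @param aggregation one of `"bma"`, `"max"`, `"average"`.
#' @inheritParams term_similarity
#' @return a single numeric similarity value.
#' @export
gene_similarity <- function(g1, g2, corpus, method,
                            aggregation = c("bma", "max", "average"),
                            dag, ic) {
  aggregation <- match.arg(aggregation)
  t1 <- intersect(corpus$direct[[g1]], names(ic$ic))
  t2 <- intersect(corpus$direct[[g2]], names(ic$ic))
  if (!length(t1) || !length(t2))
    stop("gene without scorable annotation: ",
         if (!length(t1)) g1 else g2)
  S <- term_similarity_matrix(t1, t2, method, dag, ic)
  aggregate_term_matrix(S, aggregation)
}

#' Gene-by-gene semantic similarity matrix
#'
#' Computes the full symmetric matrix of [gene_similarity()] scores for
#' all annotated genes (or a subset). Genes sharing an identical direct
#' annotation signature are scored once (signature deduplication), which
#' makes planted-module corpora fast.
#'
#' @param corpus an `annotation_corpus`.
#' @param genes genes to score (default: the corpus universe).
#' @inheritParams gene_similarity
#' @return symmetric numeric matrix with gene dimnames and attribute
#'   `measure` of the form `"<method>_<aggregation>"`.
#' @export
gene_similarity_matrix <- function(corpus, method,
                                   aggregation = c("bma", "max", "average"),
                                   dag, ic, genes = NULL) {
  aggregation <- match.arg(aggregation)
  genes <- genes %||% corpus$universe
  direct <- lapply(corpus$direct[genes], intersect, names(ic$ic))
  ok <- lengths(direct) > 0
  if (!all(ok)) {
    warning(sum(!ok), " gene(s) without scorable annotation excluded")
    genes <- genes[ok]
    direct <- direct[ok]
  }
  sig <- vapply(direct, function(ts) paste(sort(ts), collapse = "|"),
                character(1))
  usig <- unique(sig)
  sig_terms <- lapply(usig, function(s) strsplit(s, "|", fixed = TRUE)[[1]])
  # term-level cache over all distinct terms used
  all_terms <- sort(unique(unlist(sig_terms)))
  TS <- term_similarity_matrix(all_terms, all_terms, method, dag, ic)
  m <- length(usig)
  SS <- matrix(0, m, m)
  for (i in seq_len(m)) {
    ti <- sig_terms[[i]]
    for (j in i:m) {
      S <- TS[ti, sig_terms[[j]], drop = FALSE]
      SS[i, j] <- SS[j, i] <- aggregate_term_matrix(S, aggregation)
    }
  }
  idx <- match(sig, usig)
  out <- SS[idx, idx, drop = FALSE]
  dimnames(out) <- list(genes, genes)
  attr(out, "measure") <- paste0(method, "_", aggregation)
  out
}

#' Batch gene-pair semantic scorer
#'
#' Scores an explicit list of gene pairs; pairs with an unannotated gene
#' are dropped with a warning.
#'
#' @param pairs 2-column character matrix or data frame of gene pairs.
#' @inheritParams gene_similarity
#' @return data frame with columns gene1, gene2, method, aggregation,
#'   score.
#' @export
score_gene_pairs <- function(pairs, corpus, method,
                             aggregation = c("bma", "max", "average"),
                             dag, ic) {
  aggregation <- match.arg(aggregation)
  pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
  scorable <- names(Filter(function(ts) any(ts %in% names(ic$ic)),
                           corpus$direct))
  ok <- pairs[, 1] %in% scorable & pairs[, 2] %in% scorable
  if (!all(ok)) {
    warning(sum(!ok), " pair(s) with unannotated gene dropped")
    pairs <- pairs[ok, , drop = FALSE]
  }
  # one term-level similarity matrix over all used terms, then score
  # unique annotation-signature pairs once
  used_genes <- unique(c(pairs[, 1], pairs[, 2]))
  direct <- lapply(corpus$direct[used_genes], intersect, names(ic$ic))
  all_terms <- sort(unique(unlist(direct, use.names = FALSE)))
  TS <- term_similarity_matrix(all_terms, all_terms, method, dag, ic)
  tidx <- lapply(direct, match, all_terms)
  sig <- vapply(tidx, function(i) paste(sort(i), collapse = ","),
                character(1))
  s1 <- sig[pairs[, 1]]
  s2 <- sig[pairs[, 2]]
  key <- ifelse(s1 <= s2, paste(s1, s2, sep = "|"),
                paste(s2, s1, sep = "|"))
  ukey <- !duplicated(key)
  uscores <- vapply(which(ukey), function(i) {
    S <- TS[tidx[[pairs[i, 1]]], tidx[[pairs[i, 2]]], drop = FALSE]
    aggregate_term_matrix(S, aggregation)
  }, numeric(1))
  scores <- uscores[match(key, key[ukey])]
  data.frame(gene1 = pairs[, 1], gene2 = pairs[, 2],
             method = method, aggregation = aggregation,
             score = scores, stringsAsFactors = FALSE)
}
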