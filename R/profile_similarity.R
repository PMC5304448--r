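# Similarity measures on binary gene x phenotype profiles: vector-based
# (Euclidean, correlation, cosine), character-based (Hamming, Jaccard,
# Cohen's kappa), frequency-based (TF-IDF), and logistic-PCA-reduced
# vector measures.

#' Validate and construct a binary phenotype matrix
#'
#' A genes-by-phenotypes 0/1 matrix with unique row (gene) and column
#' (phenotype term) labels. A value of 1 records that knock-down of the
#' gene produced the phenotype; 0 covers both tested-absent and
#' not-tested (the screens do not distinguish them; see
#' [perturb_sparsity()] for measuring the consequence).
#'
#' @param x numeric matrix of 0/1 values with dimnames.
#' @return `x` with class `phenotype_matrix` prepended.
#' @export
phenotype_matrix <- function(x) {
  x <- as.matrix(x)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("phenotype matrix needs gene row names and phenotype column names")
  if (anyDuplicated(rownames(x)) || anyDuplicated(colnames(x)))
    stop("duplicate gene or phenotype labels")
  if (!all(x %in% c(0, 1))) stop("entries must be 0 or 1")
  storage.mode(x) <- "double"
  class(x) <- c("phenotype_matrix", class(x))
  x
}

#' Read / write the phenotype matrix TSV dialect
#'
#' Header row of phenotype term ids, first column gene id, cells 0/1.
#'
#' @param path file path.
#' @return a [phenotype_matrix()].
#' @export
read_phenotype_matrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  d <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                         check.names = FALSE, comment.char = "#")
  phenotype_matrix(as.matrix(d))
}

#' @rdname read_phenotype_matrix
#' @param mat a phenotype matrix.
#' @export
write_phenotype_matrix <- function(mat, path) {
  d <- data.frame(gene = rownames(mat), unclass(mat), check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

drop_empty_profiles <- function(mat) {
  rs <- rowSums(mat)
  if (any(rs == 0)) {
    warning(sum(rs == 0), " all-zero gene profile(s) excluded")
    mat <- mat[rs > 0, , drop = FALSE]
  }
  mat
}

#' Pairwise similarity between binary phenotype profiles
#'
#' Computes a symmetric gene-by-gene similarity matrix using one of the
#' seven profile measures:
#' \describe{
#'   \item{euclidean}{\eqn{1/(1 + ||x_1 - x_2||^2)}}
#'   \item{correlation}{Pearson correlation across phenotype positions;
#'     0 (with a warning) for zero-variance profiles}
#'   \item{cosine}{dot product over the product of norms}
#'   \item{hamming}{fraction of matching positions}
#'   \item{jaccard}{shared 1s over the union of 1s}
#'   \item{kappa}{Cohen's kappa: \eqn{(p_0 - p_c)/(1 - p_c)} with
#'     \eqn{p_0} the fraction of matching positions and chance agreement
#'     \eqn{p_c = q_1 q_2 + (1-q_1)(1-q_2)}, \eqn{q_i} the 1-fraction of
#'     profile i; 0 (with a warning) when \eqn{p_c = 1}}
#'   \item{tfidf}{\eqn{\max_p x_1^p x_2^p \mathrm{IDF}(p)} with
#'     \eqn{\mathrm{IDF}(p) = \log(n_G / (1 + \sum_g x_g^p))}; unshared
#'     phenotypes contribute 0 to the maximum, so the score is 0 when
#'     nothing is shared}
#' }
#' All-zero profiles yield 0 (with a warning) for cosine and jaccard.
#' Genes with an all-zero profile are excluded beforehand.
#'
#' @param mat a [phenotype_matrix()].
#' @param method one of `"euclidean"`, `"correlation"`, `"cosine"`,
#'   `"hamming"`, `"jaccard"`, `"kappa"`, `"tfidf"`.
#' @param drop_empty exclude all-zero rows first (default TRUE).
#' @return symmetric numeric matrix with gene dimnames; attributes
#'   `measure` and `n_degenerate` (count of degenerate pairs mapped to 0).
#' @export
profile_similarity <- function(mat,
                               method = c("euclidean", "correlation",
                                          "cosine", "hamming", "jaccard",
                                          "kappa", "tfidf"),
                               drop_empty = TRUE) {
  method <- match.arg(method)
  mat <- unclass(mat)
  if (drop_empty) mat <- drop_empty_profiles(mat)
  n_p <- ncol(mat)
  if (method == "correlation" && n_p < 2)
    stop("correlation needs at least two phenotypes")
  n_degenerate <- 0L

  s <- switch(method,
    euclidean = {
      cp <- tcrossprod(mat)
      rs <- rowSums(mat^2)
      d2 <- outer(rs, rs, "+") - 2 * cp
      1 / (1 + d2)
    },
    hamming = {
      cp <- tcrossprod(mat)
      rs <- rowSums(mat)
      mismatch <- outer(rs, rs, "+") - 2 * cp  # binary: squared = count
      (n_p - mismatch) / n_p
    },
    cosine = {
      nrm <- sqrt(rowSums(mat^2))
      bad <- nrm == 0
      nrm[bad] <- 1
      s <- tcrossprod(mat / nrm)
      if (any(bad)) {
        n_degenerate <- sum(bad) * nrow(mat)
        warning(sum(bad), " zero-norm profile(s): cosine set to 0")
        s[bad, ] <- 0; s[, bad] <- 0
      }
      s
    },
    jaccard = {
      inter <- tcrossprod(mat)
      rs <- rowSums(mat)
      uni <- outer(rs, rs, "+") - inter
      bad <- uni == 0
      if (any(bad)) {
        n_degenerate <- sum(bad)
        warning("empty-union pair(s): jaccard set to 0")
      }
      uni[bad] <- 1
      s <- inter / uni
      s[bad] <- 0
      s
    },
    correlation = {
      sds <- apply(mat, 1, stats::sd)
      bad <- sds == 0
      s <- suppressWarnings(stats::cor(t(mat)))
      if (any(bad)) {
        n_degenerate <- sum(bad) * nrow(mat)
        warning(sum(bad), " zero-variance profile(s): correlation set to 0")
      }
      s[is.na(s)] <- 0
      diag(s)[!bad] <- 1
      s
    },
    kappa = {
      cp <- tcrossprod(mat)
      rs <- rowSums(mat)
      p0 <- (n_p - (outer(rs, rs, "+") - 2 * cp)) / n_p
      q <- rs / n_p
      pc <- outer(q, q) + outer(1 - q, 1 - q)
      bad <- abs(1 - pc) < 1e-12
      if (any(bad)) {
        n_degenerate <- sum(bad)
        warning("pair(s) with chance agreement 1: kappa set to 0")
      }
      pc[bad] <- 0
      s <- (p0 - pc) / (1 - pc)
      s[bad] <- 0
      s
    },
    tfidf = {
      idf <- log(nrow(mat) / (1 + colSums(mat)))
      s <- matrix(-Inf, nrow(mat), nrow(mat))
      for (p in seq_len(n_p)) {
        v <- mat[, p]
        s <- pmax(s, tcrossprod(v) * idf[p])
      }
      # literal formula: unshared phenotypes contribute 0 to the max,
      # so the score is negative only when all phenotypes are shared
      # with negative IDF
      s[is.infinite(s)] <- 0
      s
    })

  dimnames(s) <- list(rownames(mat), rownames(mat))
  attr(s, "measure") <- method
  attr(s, "n_degenerate") <- n_degenerate
  s
}

#' Logistic PCA embedding of a binary matrix
#'
#' Fits a Bernoulli-likelihood generalization of PCA by iterative
#' majorization: the natural-parameter matrix is repeatedly replaced by
#' the rank-`k` truncated SVD of the working response
#' \eqn{Z = \Theta + 4 (X - \sigma(\Theta))} (the 1/4 bound on the
#' Bernoulli variance gives the majorizer), with a column-mean offset.
#' The embedding is the left singular vectors scaled by the singular
#' values. Initialization is deterministic (zero scores), so the result
#' is reproducible for a fixed input regardless of seed; `seed` is
#' retained in the metadata for provenance.
#'
#' @param mat a [phenotype_matrix()].
#' @param k number of components (default 10).
#' @param seed integer, recorded in attributes.
#' @param max_iter,tol majorization iteration controls.
#' @return numeric genes-by-`k` score matrix with attributes `k`, `seed`,
#'   `converged`, `deviance`.
#' @export
logistic_pca_embed <- function(mat, k = 10, seed = 1L,
                               max_iter = 500, tol = 1e-6) {
  mat <- unclass(mat)
  if (k > ncol(mat)) stop("k must not exceed the number of phenotypes")
  X <- mat
  n <- nrow(X)
  mu <- rep(0, ncol(X))
  theta <- matrix(0, n, ncol(X))
  dev_old <- Inf
  converged <- FALSE
  sigmoid <- function(z) 1 / (1 + exp(-z))
  for (it in seq_len(max_iter)) {
    eta <- sweep(theta, 2, mu, "+")
    P <- sigmoid(eta)
    Z <- eta + 4 * (X - P)
    mu <- colMeans(Z)
    Zc <- sweep(Z, 2, mu)
    sv <- svd(Zc, nu = k, nv = k)
    theta <- sv$u %*% (sv$d[seq_len(k)] * t(sv$v))
    eta <- sweep(theta, 2, mu, "+")
    P <- pmin(pmax(sigmoid(eta), 1e-12), 1 - 1e-12)
    dev <- -2 * sum(X * log(P) + (1 - X) * log(1 - P))
    if (abs(dev_old - dev) < tol * (abs(dev_old) + 1)) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  if (!converged)
    warning("logistic PCA did not converge in ", max_iter,
            " iterations; returning best iterate")
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  # sign convention: make the largest-magnitude loading of each
  # component positive so the embedding is platform-stable
  for (j in seq_len(k)) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- rownames(mat)
  structure(scores, k = k, seed = seed, converged = converged,
            deviance = dev)
}

#' Vector similarities in a reduced embedding space
#'
#' Computes euclidean (\eqn{1/(1+d^2)}), correlation or cosine similarity
#' between genes in a real-valued embedding, e.g. from
#' [logistic_pca_embed()].
#'
#' @param emb numeric genes-by-k matrix with row names.
#' @param method one of `"euclidean"`, `"correlation"`, `"cosine"`.
#' @return symmetric similarity matrix with attribute `measure`.
#' @export
embedding_similarity <- function(emb,
                                 method = c("euclidean", "correlation",
                                            "cosine")) {
  method <- match.arg(method)
  s <- switch(method,
    euclidean = {
      cp <- tcrossprod(emb)
      rs <- rowSums(emb^2)
      1 / (1 + outer(rs, rs, "+") - 2 * cp)
    },
    cosine = {
      nrm <- sqrt(rowSums(emb^2))
      nrm[nrm == 0] <- 1
      tcrossprod(emb / nrm)
    },
    correlation = {
      s <- suppressWarnings(stats::cor(t(emb)))
      s[is.na(s)] <- 0
      s
    })
  dimnames(s) <- list(rownames(emb), rownames(emb))
  attr(s, "measure") <- paste0(method, "_logpca")
  s
}

#' Sparsity perturbation of a phenotype matrix
#'
#' Sets exactly `round(fraction * #ones)` uniformly chosen 1-entries to
#' 0, emulating additional untested gene-phenotype combinations. Zero
#' entries are never modified.
#'
#' @param mat a [phenotype_matrix()].
#' @param fraction fraction of 1s to remove, in (0, 1); the study design
#'   uses 0.05, 0.10, 0.20 and 0.30.
#' @param seed integer seed.
#' @return a [phenotype_matrix()] of the same shape.
#' @export
perturb_sparsity <- function(mat, fraction, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0,1)")
  ones <- which(unclass(mat) == 1)
  if (!length(ones)) stop("matrix has no 1 entries to perturb")
  n_remove <- round(fraction * length(ones))
  drop <- with_seed(seed, sample(ones, n_remove))
  out <- unclass(mat)
  out[drop] <- 0
  phenotype_matrix(out)
}
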