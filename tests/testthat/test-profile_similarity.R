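measures7 <- c("euclidean", "correlation", "cosine", "hamming",
               "jaccard", "kappa", "tfidf")

test_that("hand-computed pair examples are reproduced", {
  m <- rbind(g1 = c(1, 0, 1), g2 = c(1, 1, 1))
  colnames(m) <- paste0("P", 1:3)
  m <- phenotype_matrix(m)
  expect_equal(profile_similarity(m, "hamming")["g1", "g2"], 2 / 3)
  expect_equal(profile_similarity(m, "jaccard")["g1", "g2"], 2 / 3)
  expect_equal(profile_similarity(m, "euclidean")["g1", "g2"], 0.5)

  # identical non-constant profiles
  m2 <- phenotype_matrix(matrix(c(1, 0, 1, 1, 0, 1), 2, byrow = TRUE,
                                dimnames = list(c("a", "b"), paste0("P", 1:3))))
  expect_equal(profile_similarity(m2, "correlation")["a", "b"], 1)
  expect_equal(profile_similarity(m2, "cosine")["a", "b"], 1)
  expect_equal(profile_similarity(m2, "kappa")["a", "b"], 1)

  # kappa zero case: p0 = pc = 0.5
  m3 <- phenotype_matrix(matrix(c(1, 1, 0, 0, 1, 0, 1, 0), 2, byrow = TRUE,
                                dimnames = list(c("a", "b"), paste0("P", 1:4))))
  expect_equal(profile_similarity(m3, "kappa")["a", "b"], 0)

  # tfidf: phenotype shared by exactly 2 of 4 genes has IDF log(4/3)
  m4 <- phenotype_matrix(matrix(c(1, 0,
                                  1, 0,
                                  0, 1,
                                  0, 1), 4, byrow = TRUE,
                                dimnames = list(paste0("g", 1:4),
                                                c("PA", "PB"))))
  expect_gte(profile_similarity(m4, "tfidf")["g1", "g2"], log(4 / 3) - 1e-12)
})

test_that("all 7 measures match the direct-formula oracle on random matrices", {
  for (seed in 1:30) {
    mat <- rand_phenotype_matrix(seed)
    for (method in measures7) {
      s <- suppressWarnings(profile_similarity(mat, method))
      expect_true(isSymmetric(unname(unclass(s))))
      for (i in 1:4) for (j in (i + 1):5)
        expect_equal(s[i, j],
                     oracle_profile_sim(unclass(mat), method, i, j),
                     tolerance = 1e-10,
                     label = paste(method, "seed", seed, i, j))
    }
  }
})

test_that("measure ranges and euclidean/hamming monotonicity hold", {
  mat <- rand_phenotype_matrix(99, n_g = 12)
  rng <- list(hamming = c(0, 1), jaccard = c(0, 1), cosine = c(0, 1),
              correlation = c(-1, 1), kappa = c(-1, 1),
              euclidean = c(0, 1))
  for (method in names(rng)) {
    s <- suppressWarnings(profile_similarity(mat, method))
    expect_true(all(s >= rng[[method]][1] - 1e-12 &
                      s <= rng[[method]][2] + 1e-12), label = method)
  }
  expect_true(all(suppressWarnings(profile_similarity(mat, "tfidf")) >=
                    min(0, log(nrow(mat) / (1 + colSums(mat))))))
  # euclidean strictly decreasing in mismatch count
  se <- profile_similarity(mat, "euclidean")
  sh <- profile_similarity(mat, "hamming")
  up <- upper.tri(se)
  mism <- (1 - sh[up]) * ncol(mat)
  expect_equal(se[up], 1 / (1 + mism), tolerance = 1e-12)
})

test_that("tfidf IDF is anti-monotone in phenotype frequency", {
  # rare-shared pair scores above common-shared pair
  m <- matrix(0, 6, 2, dimnames = list(paste0("g", 1:6), c("com", "rare")))
  m[, "com"] <- 1
  m[1:2, "rare"] <- 1
  m <- phenotype_matrix(m)
  s <- profile_similarity(m, "tfidf")
  expect_gt(s["g1", "g2"], s["g3", "g4"])
})

test_that("degenerate profiles yield 0 with warning", {
  m <- phenotype_matrix(matrix(c(1, 1, 1, 1, 0, 1), 2, byrow = TRUE,
                               dimnames = list(c("a", "b"), paste0("P", 1:3))))
  expect_warning(s <- profile_similarity(m, "correlation"),
                 "zero-variance")
  expect_equal(s["a", "b"], 0)
  expect_warning(sk <- profile_similarity(m, "kappa"), "chance agreement")
  # all-zero rows are excluded up front
  m2 <- matrix(c(1, 0, 0, 0), 2, byrow = TRUE,
               dimnames = list(c("a", "z"), c("P1", "P2")))
  expect_warning(s2 <- profile_similarity(phenotype_matrix(m2), "jaccard"),
                 "all-zero")
  expect_equal(rownames(s2), "a")
})

test_that("logistic PCA embedding honours its contracts", {
  mat <- rand_phenotype_matrix(7, n_g = 30, n_p = 8)
  emb <- suppressWarnings(logistic_pca_embed(mat, k = 4, seed = 1))
  expect_equal(dim(emb), c(30, 4))
  emb2 <- suppressWarnings(logistic_pca_embed(mat, k = 4, seed = 1))
  expect_identical(unclass(emb), unclass(emb2))  # deterministic
  expect_error(logistic_pca_embed(mat, k = 20), "exceed")

  # two disjoint phenotype blocks separate in the embedding
  m <- matrix(0, 20, 8, dimnames = list(sprintf("g%02d", 1:20),
                                        paste0("P", 1:8)))
  m[1:10, 1:4] <- 1
  m[11:20, 5:8] <- 1
  emb3 <- suppressWarnings(logistic_pca_embed(phenotype_matrix(m), k = 2,
                                              seed = 1))
  s <- embedding_similarity(emb3, "cosine")
  within <- c(s[1:10, 1:10][upper.tri(diag(10))],
              s[11:20, 11:20][upper.tri(diag(10))])
  between <- s[1:10, 11:20]
  expect_gt(mean(within), mean(between))
})

test_that("perturb_sparsity removes exactly the requested ones", {
  mat <- rand_phenotype_matrix(3)
  n1 <- sum(mat)
  out <- perturb_sparsity(mat, 0.5, seed = 4)
  expect_equal(sum(out), n1 - round(0.5 * n1))
  # determinism and zero preservation
  expect_identical(perturb_sparsity(mat, 0.05, seed = 9),
                   perturb_sparsity(mat, 0.05, seed = 9))
  out2 <- perturb_sparsity(mat, 0.2, seed = 2)
  expect_true(all(unclass(out2)[unclass(mat) == 0] == 0))
  expect_true(all(unclass(mat)[unclass(out2) == 1] == 1))
  expect_error(perturb_sparsity(mat, 1.2, seed = 1), "fraction")
  zero <- phenotype_matrix(matrix(0, 2, 2,
                                  dimnames = list(c("a", "b"),
                                                  c("P1", "P2"))))
  expect_error(perturb_sparsity(zero, 0.1, seed = 1), "no 1 entries")
})

test_that("matrix TSV round-trip preserves values and labels", {
  mat <- rand_phenotype_matrix(11)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_phenotype_matrix(mat, path)
  back <- read_phenotype_matrix(path)
  expect_equal(unclass(back), unclass(mat))
})
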