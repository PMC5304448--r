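# Synthetic inputs with planted phenotype-function structure: toy
# ontologies, annotation corpora, binary phenotype matrices and
# interaction sets, plus the packaged screen-to-phenotype fixture.

#' Configuration of the synthetic planted-module world
#'
#' Genes are partitioned into modules; each module carries a signature
#' of sibling leaf terms in both ontologies (functions and phenotypes),
#' so planted similarity is driven by deep, high-IC terms. Defaults
#' state the standard testing world: 500 genes in 8 modules, symmetric
#' annotation noise 0.1, 15% of genes partially untested, within-module
#' interaction rate 0.15 with a 0.005 cross-module background.
#'
#' @param n_genes number of genes.
#' @param n_modules number of planted modules.
#' @param noise probability that a planted 1 flips to 0 and that a
#'   background 0 flips to 1, per entry.
#' @param untested_fraction fraction of genes treated as untested in a
#'   random half of the phenotype columns (their 1s there are zeroed),
#'   emulating 0 meaning "not tested".
#' @param p_within within-module positive interaction probability.
#' @param p_background cross-module positive interaction probability
#'   (contaminating positives).
#' @param depth,branching shape of the toy ontologies.
#' @param seed integer seed; all generation is determined by it.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 500, n_modules = 8, noise = 0.1,
                             untested_fraction = 0.15,
                             p_within = 0.15, p_background = 0.005,
                             depth = 3, branching = 3, seed = 1L) {
  stopifnot(n_modules <= n_genes, noise >= 0, noise <= 1,
            untested_fraction >= 0, untested_fraction <= 1,
            p_within >= 0, p_within <= 1,
            p_background >= 0, p_background <= 1)
  structure(list(n_genes = n_genes, n_modules = n_modules, noise = noise,
                 untested_fraction = untested_fraction,
                 p_within = p_within, p_background = p_background,
                 depth = depth, branching = branching,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a toy rooted ontology DAG
#'
#' Builds a complete tree of the given depth and branching factor, then
#' adds a seeded fraction of extra is_a edges from deeper to strictly
#' shallower terms, creating multi-parent terms while guaranteeing
#' acyclicity by construction (edges always point to a smaller depth).
#'
#' @param depth tree depth (root = depth 0).
#' @param branching children per internal term; either a single number
#'   or a vector of length `depth` giving the branching factor at each
#'   level (e.g. `c(8, 3, 3)`: eight top-level subtrees, then ternary).
#' @param seed integer seed.
#' @param prefix id prefix, e.g. `"SGO"` or `"SPO"`.
#' @param extra_edge_prob per-term probability of one extra parent
#'   (default 0.1; 0 gives a pure tree).
#' @return an [onto_dag()].
#' @export
make_toy_ontology <- function(depth, branching, seed = 1L,
                              prefix = "SYN", extra_edge_prob = 0.1) {
  stopifnot(depth >= 1, all(branching >= 1))
  branching <- rep_len(branching, depth)
  level_n <- c(1, cumprod(branching))  # terms per level 0..depth
  n_terms <- sum(level_n)
  ids <- sprintf("%s:%07d", prefix, seq_len(n_terms))
  level <- rep(0:depth, level_n)
  parents <- vector("list", n_terms)
  # complete tree in level order: the j-th node of level lv hangs off
  # the ceiling(j / branching[lv])-th node of level lv-1
  offset <- cumsum(c(0, level_n))
  for (lv in seq_len(depth)) {
    idx <- which(level == lv)
    par_idx <- offset[lv] + ((seq_along(idx) - 1) %/% branching[lv]) + 1
    for (j in seq_along(idx)) parents[[idx[j]]] <- ids[par_idx[j]]
  }
  with_seed(seed, {
    for (i in which(level >= 2)) {
      if (stats::runif(1) < extra_edge_prob) {
        cand <- which(level < level[i] & ids != parents[[i]][1])
        extra <- ids[sample(cand, 1)]
        parents[[i]] <- unique(c(parents[[i]], extra))
      }
    }
  })
  names(parents) <- ids
  onto_dag(ids, parents, root = ids[[1]],
           names = stats::setNames(paste0("synthetic term ", seq_len(n_terms)),
                                   ids))
}

# leaves of a dag (terms with no children)
dag_leaves <- function(dag) {
  dag$terms[lengths(dag$children[dag$terms]) == 0]
}

#' Derive a phenotype annotation corpus from a binary matrix
#'
#' A gene's direct phenotype-ontology annotations are the terms of the
#' columns where its profile is 1; genes with all-zero profiles are
#' absent.
#'
#' @param mat a [phenotype_matrix()].
#' @param dag the phenotype `onto_dag`.
#' @return an `annotation_corpus`.
#' @export
corpus_from_matrix <- function(mat, dag) {
  m <- unclass(mat)
  direct <- lapply(seq_len(nrow(m)), function(i)
    colnames(m)[m[i, ] == 1])
  names(direct) <- rownames(m)
  direct <- direct[lengths(direct) > 0]
  propagate(direct, dag)
}

#' Generate the full planted synthetic corpus
#'
#' Splits genes into modules. For each module, a distinct deep internal
#' term of each ontology is chosen and its leaf children become the
#' module signature (functions and phenotypes respectively). Member
#' genes inherit both signatures with symmetric noise: each planted 1
#' flips to 0 with probability `noise`, each background 0 flips to 1
#' with probability `noise` (scaled by the planted/background column
#' ratio so expected spurious annotations stay bounded). A random
#' `untested_fraction` of genes have their 1s zeroed in a random half of
#' the phenotype columns, emulating genes that were not tested in some
#' screens. Positive interactions are drawn within modules at
#' `p_within` and across modules at `p_background`; negatives are an
#' equally sized uniform sample of unlabelled cross-module pairs.
#'
#' @param cfg a [synthetic_config()].
#' @param go_dag,cmpo_dag toy ontologies from [make_toy_ontology()]
#'   (default: built from `cfg`).
#' @return list with elements `go_corpus`, `cmpo_corpus`, `matrix`
#'   (a [phenotype_matrix()]), `iset` (an [interaction_set()]),
#'   `module` (named integer vector gene -> module), `go_signature`,
#'   `cmpo_signature` (per-module term sets), `go_dag`, `cmpo_dag`.
#' @export
make_planted_corpus <- function(cfg = synthetic_config(),
                                go_dag = NULL, cmpo_dag = NULL) {
  # default shape: one top-level subtree per module, so distinct modules
  # share only the root (cross-module semantic similarity bottoms out at
  # IC 0) while planted signatures sit under deep, high-IC parents
  shape <- c(cfg$n_modules, rep(cfg$branching, cfg$depth - 1))
  if (is.null(go_dag))
    go_dag <- make_toy_ontology(cfg$depth, shape,
                                seed = cfg$seed + 101L, prefix = "SGO",
                                extra_edge_prob = 0)
  if (is.null(cmpo_dag))
    cmpo_dag <- make_toy_ontology(cfg$depth, shape,
                                  seed = cfg$seed + 202L, prefix = "SPO",
                                  extra_edge_prob = 0)
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  module <- stats::setNames(rep(seq_len(cfg$n_modules),
                                length.out = cfg$n_genes), genes)

  # candidate signature parents: deepest internal terms, grouped by
  # their top-level subtree so each module draws from its own subtree
  # when the shape allows it
  sig_parents <- function(dag) {
    internal <- dag$terms[dag$depth == cfg$depth - 1 &
                            lengths(dag$children[dag$terms]) > 0]
    if (length(internal) < cfg$n_modules)
      stop("ontology too small for ", cfg$n_modules, " modules")
    top <- vapply(internal, function(t) {
      anc <- term_ancestors(dag, t)
      anc[dag$depth[anc] == 1][1]
    }, character(1))
    split(internal, top)
  }
  go_groups <- sig_parents(go_dag)
  cmpo_groups <- sig_parents(cmpo_dag)
  pick <- function(groups) {
    if (length(groups) >= cfg$n_modules)
      vapply(groups[seq_len(cfg$n_modules)],
             function(g) if (length(g) == 1) g else sample(g, 1),
             character(1))
    else sample(unlist(groups), cfg$n_modules)
  }

  with_seed(cfg$seed, {
    go_par <- pick(go_groups)
    cmpo_par <- pick(cmpo_groups)
    go_sig <- lapply(go_par, function(t) go_dag$children[[t]])
    cmpo_sig <- lapply(cmpo_par, function(t) cmpo_dag$children[[t]])

    phenos <- sort(unique(unlist(cmpo_sig)))
    n_p <- length(phenos)
    sig_size <- mean(lengths(cmpo_sig))

    # phenotype matrix with symmetric noise; background flip rate is
    # scaled so a gene gains on average `noise * sig_size` spurious 1s
    m <- matrix(0, cfg$n_genes, n_p, dimnames = list(genes, phenos))
    bg_rate <- cfg$noise * sig_size / max(1, n_p - sig_size)
    for (g in genes) {
      planted <- cmpo_sig[[module[[g]]]]
      row <- stats::setNames(numeric(n_p), phenos)
      row[planted] <- 1
      flip1 <- stats::runif(n_p) < cfg$noise
      flip0 <- stats::runif(n_p) < bg_rate
      row[row == 1 & flip1] <- 0
      row[names(row)[row == 0 & flip0]] <- 1
      if (sum(row) == 0) row[planted[[1]]] <- 1  # keep profile non-empty
      m[g, ] <- row
    }

    # untested genes: zero their 1s in a random half of the columns
    n_untested <- round(cfg$untested_fraction * cfg$n_genes)
    if (n_untested > 0) {
      ug <- sample(genes, n_untested)
      for (g in ug) {
        cols <- sample(phenos, floor(n_p / 2))
        if (all(m[g, setdiff(phenos, cols)] == 0)) next  # keep non-empty
        m[g, cols] <- 0
      }
    }

    # GO annotations: planted leaves flip off with probability `noise`;
    # spurious annotations flip on among the leaves of the annotated
    # function space (the planted signatures), mirroring the phenotype
    # matrix where noise lives in the observed columns
    go_leaves <- sort(unique(unlist(go_sig)))
    sig_size_go <- mean(lengths(go_sig))
    bg_go <- cfg$noise * sig_size_go / max(1, length(go_leaves) - sig_size_go)
    go_direct <- lapply(genes, function(g) {
      planted <- go_sig[[module[[g]]]]
      kept <- planted[stats::runif(length(planted)) >= cfg$noise]
      other <- setdiff(go_leaves, planted)
      extra <- other[stats::runif(length(other)) < bg_go]
      ts <- unique(c(kept, extra))
      if (!length(ts)) ts <- planted[[1]]
      ts
    })
    names(go_direct) <- genes

    # interactions
    up <- upper_pairs(cfg$n_genes)
    same <- module[up[, 1]] == module[up[, 2]]
    p_pair <- ifelse(same, cfg$p_within, cfg$p_background)
    is_pos <- stats::runif(nrow(up)) < p_pair
    pos <- cbind(genes[up[is_pos, 1]], genes[up[is_pos, 2]])
    cross_free <- which(!same & !is_pos)
    n_neg <- min(length(cross_free), max(1L, nrow(pos)))
    neg_idx <- sample(cross_free, n_neg)
    neg <- cbind(genes[up[neg_idx, 1]], genes[up[neg_idx, 2]])
  })

  mat <- phenotype_matrix(m)
  list(go_corpus = propagate(go_direct, go_dag),
       cmpo_corpus = corpus_from_matrix(mat, cmpo_dag),
       matrix = mat,
       iset = interaction_set(pos, neg, genes),
       module = module,
       go_signature = go_sig, cmpo_signature = cmpo_sig,
       go_dag = go_dag, cmpo_dag = cmpo_dag)
}

#' Screen-to-phenotype identifier fixture
#'
#' The packaged verbatim mapping of the seven published RNAi screens to
#' the phenotype-ontology identifiers they contribute (36 unique
#' phenotype terms in total across CellMorph, MitoCheck, the EMBL
#' secretion and chromosome-condensation screens, the Copenhagen DNA
#' damage screen and GenomeRNAi screens GR00053/GR00290).
#'
#' @return data frame with columns `screen` and `cmpo_id`.
#' @export
table1_fixture <- function() {
  rows <- list(
    CellMorph = c("CMPO:0000052", "CMPO:0000071", "CMPO:0000077",
                  "CMPO:0000083", "CMPO:0000105", "CMPO:0000118",
                  "CMPO:0000128", "CMPO:0000129", "CMPO:0000154",
                  "CMPO:0000305", "CMPO:0000340"),
    MitoCheck = c("CMPO:0000030", "CMPO:0000140", "CMPO:0000156",
                  "CMPO:0000157", "CMPO:0000202", "CMPO:0000213",
                  "CMPO:0000216", "CMPO:0000236", "CMPO:0000237",
                  "CMPO:0000241", "CMPO:0000307", "CMPO:0000326",
                  "CMPO:0000344", "CMPO:0000345", "CMPO:0000348"),
    `EMBL secretion` = c("CMPO:0000246", "CMPO:0000318",
                         "CMPO:0000319", "CMPO:0000346"),
    GR00053 = "CMPO:0000182",
    GR00290 = c("CMPO:0000361", "CMPO:0000362"),
    `Copenhagen DNA damage Ubiquitin` = "CMPO:0000181",
    `EMBL chromosome condensation` = c("CMPO:0000328", "CMPO:0000329"))
  data.frame(screen = rep(names(rows), lengths(rows)),
             cmpo_id = unlist(rows, use.names = FALSE),
             stringsAsFactors = FALSE)
}
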