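# Ontology DAG handling: OBO parsing, ancestor closure, annotation
# propagation, information content and most-informative common ancestors.

#' Construct an ontology DAG
#'
#' Builds a rooted directed acyclic graph of ontology terms from
#' child-to-parent `is_a` relations. Ancestor sets (excluding self) are
#' precomputed for every term. Used directly by [make_toy_ontology()] and
#' by [parse_obo()].
#'
#' @param terms character vector of term identifiers.
#' @param parents named list mapping each term to the character vector of
#'   its `is_a` parents (empty for the root).
#' @param root the root term identifier.
#' @param names optional named character vector of term labels.
#' @param obsolete character vector of obsolete term ids (excluded from
#'   `terms`; recorded for provenance).
#' @return an object of class `onto_dag` with elements `terms`, `parents`,
#'   `children`, `ancestors` (per-term ancestors excluding self), `root`,
#'   `names`, `obsolete`, `depth`.
#' @export
onto_dag <- function(terms, parents, root, names = NULL,
                     obsolete = character(0)) {
  terms <- unique(as.character(terms))
  if (!root %in% terms) stop("root term '", root, "' not among terms")
  parents <- parents[terms]
  names(parents) <- terms
  parents <- lapply(parents, function(p) {
    p <- intersect(as.character(p %||% character(0)), terms)
    p
  })
  children <- vector("list", length(terms))
  names(children) <- terms
  for (t in terms) for (p in parents[[t]]) children[[p]] <- c(children[[p]], t)

  # topological order by Kahn's algorithm; detects cycles
  indeg <- vapply(parents, length, integer(1))
  queue <- terms[indeg == 0L]
  order <- character(0)
  indeg_work <- indeg
  while (length(queue)) {
    t <- queue[[1]]; queue <- queue[-1]
    order <- c(order, t)
    for (ch in children[[t]]) {
      indeg_work[[ch]] <- indeg_work[[ch]] - 1L
      if (indeg_work[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < length(terms)) {
    bad <- setdiff(terms, order)[[1]]
    stop("cycle detected in ontology involving edge at term '", bad, "'")
  }

  ancestors <- vector("list", length(terms))
  names(ancestors) <- terms
  for (t in order) {
    anc <- character(0)
    for (p in parents[[t]]) anc <- c(anc, p, ancestors[[p]])
    ancestors[[t]] <- unique(anc)
  }
  depth <- vapply(terms, function(t) length(ancestors[[t]]), integer(1))

  non_root <- setdiff(terms, root)
  unreachable <- non_root[!vapply(ancestors[non_root],
                                  function(a) root %in% a, logical(1))]
  if (length(unreachable))
    stop(length(unreachable), " term(s) have no path to root, e.g. '",
         unreachable[[1]], "'")

  structure(list(terms = terms, parents = parents, children = children,
                 ancestors = ancestors, root = root,
                 names = names %||% stats::setNames(terms, terms),
                 obsolete = obsolete, depth = depth),
            class = "onto_dag")
}

#' @export
print.onto_dag <- function(x, ...) {
  cat("Ontology DAG:", length(x$terms), "terms, root", x$root, "\n")
  invisible(x)
}

#' Ancestors of a term
#'
#' @param dag an `onto_dag`.
#' @param term a term identifier.
#' @param include_self include the term itself (default TRUE).
#' @return character vector of ancestor term ids.
#' @export
term_ancestors <- function(dag, term, include_self = TRUE) {
  if (!term %in% dag$terms) stop("term '", term, "' not in ontology")
  a <- dag$ancestors[[term]]
  if (include_self) c(term, a) else a
}

#' Parse an OBO-format ontology file
#'
#' Reads `[Term]` stanzas (fields: `id`, `name`, `is_a`, `is_obsolete`)
#' of an OBO 1.2/1.4 file. Obsolete terms are excluded together with all
#' edges touching them. When `root` is given, the DAG is restricted to
#' the terms from which `root` is reachable via `is_a` (the root's
#' descendant closure, root included). Only `is_a` relations are
#' traversed; `part_of` and other relationship types are ignored.
#'
#' @param path path to an OBO file.
#' @param root optional root term id for branch restriction.
#' @return an [onto_dag()].
#' @export
parse_obo <- function(path, root = NULL) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  in_term <- FALSE
  cur <- NULL
  stanzas <- list()
  flush <- function(cur, stanzas) {
    if (!is.null(cur) && !is.null(cur$id)) stanzas[[cur$id]] <- cur
    stanzas
  }
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)  # trailing comments
    ln <- trimws(ln)
    if (ln == "[Term]") {
      stanzas <- flush(cur, stanzas)
      cur <- list(id = NULL, name = NA_character_, is_a = character(0),
                  obsolete = FALSE)
      in_term <- TRUE
      next
    }
    if (grepl("^\\[", ln)) {  # other stanza type
      stanzas <- flush(cur, stanzas)
      cur <- NULL; in_term <- FALSE
      next
    }
    if (!in_term || ln == "") next
    if (grepl("^id:", ln)) cur$id <- trimws(sub("^id:", "", ln))
    else if (grepl("^name:", ln)) cur$name <- trimws(sub("^name:", "", ln))
    else if (grepl("^is_a:", ln)) {
      tgt <- trimws(sub("^is_a:", "", ln))
      tgt <- strsplit(tgt, "\\s+")[[1]][1]
      cur$is_a <- c(cur$is_a, tgt)
    } else if (grepl("^is_obsolete:", ln)) {
      cur$obsolete <- grepl("true", ln, fixed = TRUE)
    }
  }
  stanzas <- flush(cur, stanzas)
  if (!length(stanzas)) stop("no [Term] stanzas found in ", path)

  obsolete <- names(stanzas)[vapply(stanzas, `[[`, logical(1), "obsolete")]
  keep <- setdiff(names(stanzas), obsolete)
  parents <- lapply(stanzas[keep], function(s) setdiff(s$is_a, obsolete))
  labels <- vapply(stanzas[keep], `[[`, character(1), "name")
  names(labels) <- keep

  if (!is.null(root)) {
    if (!root %in% keep) stop("root term '", root, "' absent from file")
    # keep terms from which root is reachable: iterate children closure
    child_map <- list()
    for (t in keep) for (p in intersect(parents[[t]], keep))
      child_map[[p]] <- c(child_map[[p]], t)
    sel <- character(0)
    queue <- root
    while (length(queue)) {
      t <- queue[[1]]; queue <- queue[-1]
      if (t %in% sel) next
      sel <- c(sel, t)
      queue <- c(queue, child_map[[t]])
    }
    keep <- sel
    parents <- lapply(parents[keep], intersect, keep)
    names(parents) <- keep
    labels <- labels[keep]
  } else {
    # use a term with no parents as root; require it to be unique
    roots <- keep[vapply(parents[keep],
                         function(p) length(intersect(p, keep)) == 0L,
                         logical(1))]
    if (length(roots) != 1L)
      stop("ontology has ", length(roots),
           " parentless terms; supply `root` explicitly")
    root <- roots
  }
  onto_dag(keep, parents, root, names = labels, obsolete = obsolete)
}

#' Write an ontology as a minimal OBO file
#'
#' Emits the dialect [parse_obo()] consumes, so synthetic and real runs
#' share one reader code path.
#'
#' @param dag an `onto_dag`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2\n", con)
  for (t in dag$terms) {
    writeLines(c("[Term]", paste0("id: ", t),
                 paste0("name: ", dag$names[[t]] %||% t),
                 paste0("is_a: ", dag$parents[[t]]), ""), con)
  }
  invisible(path)
}

#' Read gene annotations
#'
#' `read_gaf()` reads GAF 2.x (columns 2 = gene, 5 = term, 7 = evidence
#' code), dropping rows whose evidence code is in `exclude_evidence`
#' (default: IEA, electronically-inferred annotations).
#' `read_annotation_tsv()` reads a minimal two-column
#' `gene<TAB>term` dialect with no evidence filtering.
#'
#' @param path file path.
#' @param exclude_evidence evidence codes to drop (GAF only).
#' @return named list mapping gene to character vector of term ids.
#' @export
read_gaf <- function(path, exclude_evidence = "IEA") {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^!", lines) & nzchar(lines)]
  if (!length(lines)) stop("no annotation rows in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(fields, function(f)
    length(f) >= 7 && !(f[[7]] %in% exclude_evidence), logical(1))
  fields <- fields[keep]
  genes <- vapply(fields, `[[`, character(1), 2)
  terms <- vapply(fields, `[[`, character(1), 5)
  split(terms, genes)
}

#' @rdname read_gaf
#' @export
read_annotation_tsv <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, comment.char = "#",
                         col.names = c("gene", "term"),
                         colClasses = "character")
  split(d$term, d$gene)
}

#' Write a two-column annotation TSV
#'
#' @param direct named list gene -> term ids.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(direct, path) {
  genes <- rep(names(direct), lengths(direct))
  utils::write.table(data.frame(gene = genes, term = unlist(direct)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Propagate gene annotations to ontology ancestors
#'
#' Closes each gene's direct annotation set under the is_a ancestor
#' relation, so that a term's gene count includes genes annotated to any
#' of its descendants. Annotated terms absent from the DAG (e.g. from a
#' different ontology branch) are dropped with a warning; genes left with
#' no in-DAG annotation are removed from the universe.
#'
#' @param direct named list mapping gene to character vector of term ids.
#' @param dag an `onto_dag`.
#' @param evidence_filter record of excluded evidence codes (metadata only).
#' @return object of class `annotation_corpus` with elements `direct`,
#'   `propagated`, `universe`, `evidence_filter`.
#' @export
propagate <- function(direct, dag, evidence_filter = character(0)) {
  if (!length(direct)) stop("empty annotation corpus")
  direct <- lapply(direct, function(ts) unique(as.character(ts)))
  dropped <- sum(vapply(direct, function(ts)
    sum(!ts %in% dag$terms), integer(1)))
  if (dropped > 0)
    warning(dropped, " annotation(s) to terms outside the DAG dropped")
  direct <- lapply(direct, intersect, dag$terms)
  direct <- direct[lengths(direct) > 0]
  if (!length(direct)) stop("no annotations remain after DAG restriction")
  propagated <- lapply(direct, function(ts)
    unique(c(ts, unlist(dag$ancestors[ts], use.names = FALSE))))
  structure(list(direct = direct, propagated = propagated,
                 universe = names(direct),
                 evidence_filter = evidence_filter),
            class = "annotation_corpus")
}

#' @export
print.annotation_corpus <- function(x, ...) {
  cat("Annotation corpus:", length(x$universe), "genes,",
      length(unique(unlist(x$direct))), "directly used terms\n")
  invisible(x)
}

#' Annotation-based information content
#'
#' For every term with at least one (ancestor-propagated) annotated
#' gene: `p(t) = annotated_genes(t) / total_annotated_genes` and
#' `ic(t) = -log p(t)` in nats. `annotations(t)` counts distinct genes
#' after propagation, so IC is monotone non-decreasing from root to
#' leaves and `ic(root) = 0` when all genes reach the root.
#'
#' @param corpus an `annotation_corpus`.
#' @param dag an `onto_dag`.
#' @return object of class `term_ic` with named numeric vectors `ic` and
#'   `p`, and `n_genes` (universe size).
#' @export
compute_ic <- function(corpus, dag) {
  if (!inherits(corpus, "annotation_corpus")) stop("need an annotation_corpus")
  counts <- table(unlist(lapply(corpus$propagated, unique),
                         use.names = FALSE))
  counts <- counts[names(counts) %in% dag$terms]
  n <- length(corpus$universe)
  p <- as.numeric(counts) / n
  names(p) <- names(counts)
  structure(list(ic = -log(p), p = p, n_genes = n), class = "term_ic")
}

#' Most informative common ancestor of two terms
#'
#' Returns the common ancestor-or-self of `t1` and `t2` with maximal
#' information content; ties are broken by the lexicographically
#' smallest term id.
#'
#' @param t1,t2 term identifiers (must be in `ic`'s domain).
#' @param dag an `onto_dag`.
#' @param ic a `term_ic`.
#' @return list with elements `term` and `ic`.
#' @export
mica <- function(t1, t2, dag, ic) {
  common <- intersect(term_ancestors(dag, t1), term_ancestors(dag, t2))
  common <- common[common %in% names(ic$ic)]
  if (!length(common)) stop("terms '", t1, "' and '", t2,
                            "' have no common ancestor with defined IC")
  vals <- ic$ic[common]
  best <- common[vals == max(vals)]
  t <- sort(best)[[1]]
  list(term = t, ic = unname(ic$ic[[t]]))
}
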