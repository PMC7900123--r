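# Ontology handling and topology-aware GO term enrichment.

#' Construct an ontology DAG
#'
#' @param terms Character vector of term ids.
#' @param parents Named list mapping each term to its `is_a` parents (the
#'   root maps to none). Must be acyclic with every term reaching one root.
#' @param names Optional named character vector of term names.
#' @return Object of class `ontology_dag` with `terms`, `parents`,
#'   `children`, `root`, `name`.
#' @export
ontology_dag <- function(terms, parents, names = NULL) {
  stopifnot(all(names(parents) %in% terms))
  parents <- parents[terms]
  names(parents) <- terms
  parents <- lapply(parents, function(p) as.character(p %||% character(0)))
  bad <- setdiff(unique(unlist(parents)), terms)
  if (length(bad)) stop_config("parent term(s) not in DAG: %s", bad[1L])
  roots <- terms[lengths(parents) == 0L]
  if (length(roots) != 1L) {
    stop_config("ontology must have exactly one root (found %d)", length(roots))
  }
  children <- stats::setNames(vector("list", length(terms)), terms)
  for (t in terms) {
    for (p in parents[[t]]) children[[p]] <- c(children[[p]], t)
  }
  dag <- structure(list(terms = terms, parents = parents,
                        children = children, root = roots,
                        name = names %||% stats::setNames(terms, terms)),
                   class = "ontology_dag")
  # reject cycles and unreachable terms up front
  lv <- dag_levels(dag)
  if (any(is.na(lv))) stop_config("ontology contains a cycle or unreachable term")
  dag
}

# Level = 1 + length of the longest path from the root (root is level 1).
dag_levels <- function(dag) {
  lv <- stats::setNames(rep(NA_integer_, length(dag$terms)), dag$terms)
  lv[dag$root] <- 1L
  remaining <- setdiff(dag$terms, dag$root)
  guard <- 0L
  while (length(remaining) > 0L) {
    progressed <- FALSE
    for (t in remaining) {
      pl <- lv[dag$parents[[t]]]
      if (!anyNA(pl)) {
        lv[t] <- max(pl) + 1L
        progressed <- TRUE
      }
    }
    remaining <- names(lv)[is.na(lv)]
    guard <- guard + 1L
    if (!progressed || guard > length(dag$terms) + 1L) break
  }
  lv
}

#' Ancestors of a term (excluding the term itself)
#' @param dag An `ontology_dag`.
#' @param term Term id.
#' @export
go_ancestors <- function(dag, term) {
  out <- character(0)
  frontier <- dag$parents[[term]]
  while (length(frontier)) {
    out <- union(out, frontier)
    frontier <- unique(unlist(dag$parents[frontier], use.names = FALSE))
    frontier <- setdiff(frontier, out)
  }
  out
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("ontology_dag: %d terms, root %s, depth %d\n",
              length(x$terms), x$root, max(dag_levels(x))))
  invisible(x)
}

#' Write an ontology as minimal OBO
#'
#' Emits `[Term]` stanzas with `id`, `name` and `is_a` lines, sufficient for
#' round-tripping the DAG.
#' @param dag An `ontology_dag`.
#' @param path Output path.
#' @export
write_obo <- function(dag, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", "ontology: synthetic", ""), con)
  for (t in dag$terms) {
    writeLines(c("[Term]",
                 paste0("id: ", t),
                 paste0("name: ", dag$name[[t]]),
                 vapply(dag$parents[[t]], function(p)
                   paste0("is_a: ", p, " ! ", dag$name[[p]]), character(1)),
                 ""), con)
  }
  invisible(path)
}

#' Read a minimal OBO file
#'
#' Parses `[Term]` stanzas (`id`, `name`, `is_a`); other stanza types and
#' tags are ignored. Obsolete terms are dropped.
#' @param path OBO path.
#' @return An `ontology_dag`.
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  terms <- character(0)
  nms <- character(0)
  parents <- list()
  cur <- NULL
  in_term <- FALSE
  obsolete <- character(0)
  flush <- function() {
    if (!is.null(cur) && nzchar(cur$id)) {
      terms <<- c(terms, cur$id)
      nms[cur$id] <<- cur$name
      parents[[cur$id]] <<- cur$is_a
      if (cur$obsolete) obsolete <<- c(obsolete, cur$id)
    }
  }
  for (ln in lines) {
    ln <- sub("\\s+$", "", ln)
    if (ln == "[Term]") {
      flush()
      cur <- list(id = "", name = "", is_a = character(0), obsolete = FALSE)
      in_term <- TRUE
    } else if (grepl("^\\[", ln)) {
      flush(); cur <- NULL; in_term <- FALSE
    } else if (in_term && !is.null(cur)) {
      if (startsWith(ln, "id: ")) cur$id <- sub("^id: ", "", ln)
      if (startsWith(ln, "name: ")) cur$name <- sub("^name: ", "", ln)
      if (startsWith(ln, "is_a: ")) {
        tgt <- sub("^is_a: *([^ !]+).*$", "\\1", ln)
        cur$is_a <- c(cur$is_a, tgt)
      }
      if (startsWith(ln, "is_obsolete: true")) cur$obsolete <- TRUE
    }
  }
  flush()
  keep <- setdiff(terms, obsolete)
  ontology_dag(keep, parents[keep], nms[keep])
}

#' Read a two-column gene-to-term annotation table
#'
#' Expects tab-separated `gene_id<TAB>term_id` (one pair per line, `#`
#' comments allowed); multiple terms per gene on separate lines.
#' @param path TSV path.
#' @return Named list gene -> character vector of directly annotated terms.
#' @export
read_gene2go <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_config("gene2go file must have two columns")
  split(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Propagate annotations up the ontology (true-path rule)
#'
#' A gene annotated to a term is implicitly annotated to every ancestor of
#' that term; the operation is idempotent.
#'
#' @param gene2go Named list gene -> direct terms.
#' @param dag An `ontology_dag`.
#' @param unknown What to do with annotations to terms missing from the DAG:
#'   `"drop"` (with a warning) or `"error"`.
#' @return Object of class `annotation_map`: list with `gene2terms`
#'   (closed gene -> terms), `term2genes` (term -> genes), and `universe`
#'   (genes with at least one term).
#' @export
propagate_annotations <- function(gene2go, dag,
                                  unknown = c("drop", "error")) {
  unknown <- match.arg(unknown)
  all_terms <- unlist(gene2go, use.names = FALSE)
  missing <- setdiff(unique(all_terms), dag$terms)
  if (length(missing)) {
    if (unknown == "error") {
      stop_config("annotation to unknown term %s", missing[1L])
    }
    warning(sprintf("%d annotation term(s) not in the ontology dropped",
                    length(missing)), call. = FALSE)
  }
  anc_cache <- new.env(parent = emptyenv())
  closure <- function(t) {
    if (!is.null(anc_cache[[t]])) return(anc_cache[[t]])
    v <- c(t, go_ancestors(dag, t))
    anc_cache[[t]] <- v
    v
  }
  gene2terms <- lapply(gene2go, function(ts) {
    ts <- intersect(unique(ts), dag$terms)
    if (length(ts) == 0L) return(character(0))
    unique(unlist(lapply(ts, closure), use.names = FALSE))
  })
  gene2terms <- gene2terms[lengths(gene2terms) > 0L]
  term2genes <- list()
  if (length(gene2terms)) {
    long_terms <- unlist(gene2terms, use.names = FALSE)
    long_genes <- rep(names(gene2terms), lengths(gene2terms))
    term2genes <- split(long_genes, long_terms)
  }
  structure(list(gene2terms = gene2terms, term2genes = term2genes,
                 universe = names(gene2terms)),
            class = "annotation_map")
}

# One-sided over-representation p-value from the hypergeometric tail.
fisher_over <- function(sig, ann, universe_n, study_n) {
  stats::phyper(sig - 1, ann, universe_n - ann, study_n, lower.tail = FALSE)
}

#' Classic Fisher over-representation test per term
#'
#' One-sided p-value for each term with at least `min_annotated` genes in the
#' universe, from the 2x2 table of study/term membership.
#'
#' @param study Character vector of study genes (must be within the
#'   universe).
#' @param ann An [propagate_annotations()] result.
#' @param min_annotated Terms with fewer universe genes are skipped
#'   (default 2).
#' @return Data frame: `term`, `annotated`, `significant`, `expected`,
#'   `p_classic`.
#' @export
fisher_classic <- function(study, ann, min_annotated = 2L) {
  stopifnot(inherits(ann, "annotation_map"))
  universe <- ann$universe
  if (length(universe) == 0L) stop_config("empty universe")
  study <- intersect(unique(study), universe)
  if (length(study) == 0L) stop_config("empty study set (after universe restriction)")
  n_u <- length(universe)
  n_s <- length(study)
  terms <- names(ann$term2genes)
  annotated <- lengths(ann$term2genes)
  keep <- annotated >= min_annotated
  terms <- terms[keep]
  annotated <- annotated[keep]
  significant <- vapply(ann$term2genes[terms], function(g)
    length(intersect(g, study)), numeric(1))
  data.frame(
    term = terms,
    annotated = as.numeric(annotated),
    significant = as.numeric(significant),
    expected = as.numeric(annotated) * n_s / n_u,
    p_classic = fisher_over(significant, annotated, n_u, n_s),
    row.names = NULL, stringsAsFactors = FALSE)
}

# Weighted Fisher: term-member counts are sums of per-gene weights, rounded
# to integers before the hypergeometric tail (the universe and study sizes
# stay integral).
weighted_fisher <- function(w, study_lookup, universe_n, study_n) {
  sig <- round(sum(w[study_lookup[names(w)]]))
  annv <- round(sum(w))
  annv <- max(annv, sig)
  max(fisher_over(sig, annv, universe_n, study_n), 1e-300)
}

#' Topology-decorrelated enrichment (weight algorithm)
#'
#' Processes terms bottom-up by level (longest path from the root). At each
#' term the locally computed significance is compared with that of its
#' already-processed children: genes supporting whichever side is less
#' significant are down-weighted by the significance ratio before the term's
#' weighted Fisher statistic is recomputed, so a parent whose signal is fully
#' explained by a child is not reported again. On a flat ontology the result
#' equals the classic Fisher test.
#'
#' @inheritParams fisher_classic
#' @param dag The `ontology_dag` the annotations were propagated on.
#' @return The [fisher_classic()] frame with an extra `p_weight` column.
#' @export
weight_enrichment <- function(dag, study, ann, min_annotated = 2L) {
  base <- fisher_classic(study, ann, min_annotated = min_annotated)
  universe <- ann$universe
  study <- intersect(unique(study), universe)
  n_u <- length(universe)
  n_s <- length(study)
  study_lookup <- stats::setNames(rep(FALSE, n_u), universe)
  study_lookup[study] <- TRUE

  testable <- base$term
  weights <- lapply(stats::setNames(testable, testable), function(t) {
    g <- ann$term2genes[[t]]
    stats::setNames(rep(1, length(g)), g)
  })
  p_store <- stats::setNames(rep(NA_real_, length(testable)), testable)

  lv <- dag_levels(dag)
  order_terms <- testable[order(-lv[testable])]
  children_of <- function(u) {
    # testable descendants reached through untestable intermediates collapse
    # onto their nearest testable ancestor
    out <- character(0)
    frontier <- dag$children[[u]] %||% character(0)
    while (length(frontier)) {
      t_ok <- frontier %in% testable
      out <- union(out, frontier[t_ok])
      frontier <- unique(unlist(dag$children[frontier[!t_ok]],
                                use.names = FALSE))
    }
    out
  }
  anc_of <- function(u) intersect(go_ancestors(dag, u), testable)

  compute_term_sig <- function(u, ch) {
    p_u <- weighted_fisher(weights[[u]], study_lookup, n_u, n_s)
    if (length(ch) == 0L) {
      p_store[u] <<- p_u
      return(invisible(NULL))
    }
    ratio <- p_u / pmax(p_store[ch], 1e-300)
    if (all(ratio <= 1)) {
      # u at least as significant as every child: down-weight the weaker
      # children's genes and re-record their p-values
      for (ci in which(ratio < 1)) {
        c_term <- ch[ci]
        weights[[c_term]] <<- weights[[c_term]] * ratio[ci]
        p_store[c_term] <<- weighted_fisher(weights[[c_term]], study_lookup,
                                            n_u, n_s)
      }
      p_store[u] <<- p_u
      return(invisible(NULL))
    }
    # some child explains the signal better: down-weight its genes in u and
    # all ancestors of u, then re-test u against the remaining children
    stronger <- ch[ratio > 1]
    for (c_term in stronger) {
      gs <- intersect(names(weights[[c_term]]), names(weights[[u]]))
      r <- ratio[match(c_term, ch)]
      for (a in c(u, anc_of(u))) {
        in_a <- intersect(gs, names(weights[[a]]))
        if (length(in_a)) weights[[a]][in_a] <<- weights[[a]][in_a] / r
      }
    }
    compute_term_sig(u, setdiff(ch, stronger))
  }

  for (u in order_terms) {
    ch <- children_of(u)
    ch <- ch[!is.na(p_store[ch])]
    compute_term_sig(u, ch)
  }
  base$p_weight <- as.numeric(p_store[base$term])
  base
}

#' Elim enrichment: remove significant children's genes from ancestors
#'
#' Bottom-up traversal; whenever a term tests at or below `elim_cutoff`, its
#' genes are eliminated from all its ancestors before those are tested.
#'
#' @inheritParams weight_enrichment
#' @param elim_cutoff Elimination threshold (default 0.01).
#' @return The [fisher_classic()] frame with an extra `p_elim` column.
#' @export
elim_enrichment <- function(dag, study, ann, min_annotated = 2L,
                            elim_cutoff = 0.01) {
  base <- fisher_classic(study, ann, min_annotated = min_annotated)
  universe <- ann$universe
  study <- intersect(unique(study), universe)
  n_u <- length(universe)
  n_s <- length(study)
  lv <- dag_levels(dag)
  order_terms <- base$term[order(-lv[base$term])]
  eliminated <- stats::setNames(vector("list", length(base$term)), base$term)
  p_out <- stats::setNames(rep(NA_real_, length(base$term)), base$term)
  for (u in order_terms) {
    genes <- setdiff(ann$term2genes[[u]], eliminated[[u]])
    sig <- length(intersect(genes, study))
    p <- fisher_over(sig, length(genes), n_u, n_s)
    p_out[u] <- p
    if (p <= elim_cutoff) {
      for (a in intersect(go_ancestors(dag, u), base$term)) {
        eliminated[[a]] <- union(eliminated[[a]], ann$term2genes[[u]])
      }
    }
  }
  base$p_elim <- as.numeric(p_out[base$term])
  base
}

#' Run a GO enrichment analysis
#'
#' Restricts the study set to the universe (all genes with at least one GO
#' term), runs the classic Fisher test and the chosen topology method.
#'
#' @param dag An `ontology_dag`.
#' @param gene2go Named list gene -> direct terms (or an `annotation_map`).
#' @param study Character vector of study genes.
#' @param method `"weight"` (default), `"elim"` or `"classic"`.
#' @param min_annotated Minimum universe genes per testable term (default 2).
#' @return Data frame of class `enrichment_result`: `term`, `name`,
#'   `annotated`, `significant`, `expected`, `p_classic`, `p_method`.
#' @export
go_enrichment <- function(dag, gene2go, study,
                          method = c("weight", "elim", "classic"),
                          min_annotated = 2L) {
  method <- match.arg(method)
  ann <- if (inherits(gene2go, "annotation_map")) gene2go else
    propagate_annotations(gene2go, dag)
  res <- switch(method,
    weight = {
      r <- weight_enrichment(dag, study, ann, min_annotated)
      r$p_method <- r$p_weight
      r
    },
    elim = {
      r <- elim_enrichment(dag, study, ann, min_annotated)
      r$p_method <- r$p_elim
      r
    },
    classic = {
      r <- fisher_classic(study, ann, min_annotated)
      r$p_method <- r$p_classic
      r
    })
  res$name <- as.character(dag$name[res$term])
  res <- res[, c("term", "name", "annotated", "significant", "expected",
                 "p_classic", "p_method")]
  attr(res, "method") <- method
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Report enriched terms at a raw p-value cutoff
#'
#' Sorted ascending by the method p-value; no multiple-testing correction is
#' applied by default (a raw cutoff is the convention this pipeline follows);
#' pass `correct = "BH"` etc. to adjust first.
#'
#' @param results An `enrichment_result`.
#' @param alpha Cutoff (default 0.001).
#' @param correct Optional [stats::p.adjust()] method applied to `p_method`
#'   before filtering (default `"none"`).
#' @return The filtered, sorted subset of `results`.
#' @export
enrichment_report <- function(results, alpha = 0.001, correct = "none") {
  stopifnot(inherits(results, "enrichment_result"))
  p <- results$p_method
  if (!identical(correct, "none")) p <- stats::p.adjust(p, method = correct)
  out <- results[p <= alpha, , drop = FALSE]
  out[order(out$p_method), , drop = FALSE]
}
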