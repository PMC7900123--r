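# Synthetic ontology generation: a single-rooted acyclic is_a DAG.

#' Generate a synthetic ontology DAG
#'
#' Builds a single-rooted acyclic `is_a` DAG with `n_go_terms` terms spread
#' over `dag_depth` levels; every non-root term has one parent on the level
#' above and, with some probability, a second parent on any shallower level
#' (so the graph is a proper DAG, not a tree). Deterministic given the
#' config seed.
#'
#' @param config A [sim_config()].
#' @return An [ontology_dag()].
#' @export
generate_ontology <- function(config) {
  validate_sim_config(config)
  n <- as.integer(config$n_go_terms)
  if (n < 1) stop_config("n_go_terms must be >= 1")
  set.seed(config$seed + 101L)
  ids <- sprintf("GO:%07d", seq_len(n))
  nms <- stats::setNames(c("synthetic process root",
                           sprintf("synthetic process %d", seq_len(max(0, n - 1)))),
                         ids)
  if (n == 1L) {
    return(ontology_dag(ids, stats::setNames(list(character(0)), ids), nms))
  }
  depth <- min(as.integer(config$dag_depth), n)
  # assign levels: root at 1, at least one term per level, rest random
  level <- integer(n)
  level[1L] <- 1L
  level[2:min(depth, n)] <- 2:min(depth, n)
  if (n > depth) {
    level[(depth + 1L):n] <- sample_from(2:depth, n - depth, replace = TRUE)
  }
  level <- c(1L, sort(level[-1L]))
  parents <- stats::setNames(vector("list", n), ids)
  parents[[ids[1L]]] <- character(0)
  for (i in 2:n) {
    above <- which(level == level[i] - 1L)
    shallower <- which(level < level[i])
    p <- sample_from(ids[above], 1L)
    if (length(shallower) > 1L && runif(1) < 0.3) {
      extra <- sample_from(ids[setdiff(shallower, match(p, ids))], 1L)
      p <- unique(c(p, extra))
    }
    parents[[ids[i]]] <- p
  }
  ontology_dag(ids, parents, nms)
}

# Leaf terms (no children), deepest first; used to pick enrichment targets.
dag_leaves <- function(dag) {
  leaves <- dag$terms[lengths(dag$children[dag$terms]) == 0L]
  lv <- dag_levels(dag)
  leaves[order(-lv[leaves])]
}
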