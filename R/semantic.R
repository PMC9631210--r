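#' Build the ancestor DAG of a disease with decayed semantic contributions
#'
#' Starting from a disease term, the rooted DAG contains the disease and
#' all ontology ancestors reachable through child-to-parent edges. Each
#' node receives a semantic contribution: the disease itself contributes
#' 1, and every ancestor `t` contributes `gamma` times the maximum
#' contribution among `t`'s children inside the DAG (Wang-style decay).
#' Contributions therefore lie in `(0, 1]` and shrink with distance from
#' the query disease.
#'
#' A disease absent from the ontology edge list is treated as an isolated
#' term whose DAG is the singleton `{disease}` (contribution 1), unless
#' `require_known = TRUE`, in which case a lookup error is raised.
#'
#' @param disease disease identifier (character scalar).
#' @param ontology data frame with columns `child`, `parent`
#'   (see [read_ontology()]), or a path to such a file.
#' @param gamma semantic decay factor in (0, 1); default 0.5.
#' @param require_known error if `disease` appears in no ontology edge.
#' @return object of class `"disease_dag"`: a list with `disease_id`,
#'   `nodes`, `edges` (restricted to the DAG), `contributions` (named
#'   numeric), and `gamma`.
#' @examples
#' ont <- data.frame(child = c("d", "p"), parent = c("p", "g"))
#' dag <- build_disease_dag("d", ont, gamma = 0.5)
#' dag$contributions  # d = 1, p = 0.5, g = 0.25
#' @export
build_disease_dag <- function(disease, ontology, gamma = 0.5,
                              require_known = FALSE) {
  if (is.character(ontology) && length(ontology) == 1) {
    ontology <- read_ontology(ontology)
  }
  if (!(gamma > 0 && gamma < 1)) {
    stop_ldapred("gamma must lie in (0, 1)", "input_error")
  }
  disease <- as.character(disease)
  if (length(disease) != 1 || is.na(disease) || !nzchar(disease)) {
    stop_ldapred("disease must be a single non-empty identifier", "lookup_error")
  }
  child <- as.character(ontology$child)
  parent <- as.character(ontology$parent)
  if (require_known && !(disease %in% c(child, parent))) {
    stop_ldapred(paste0("disease '", disease, "' not found in the ontology"),
                 "lookup_error")
  }

  # collect ancestors by upward traversal (child -> parent)
  parents_of <- split(parent, child)
  nodes <- character(0)
  frontier <- disease
  while (length(frontier)) {
    nodes <- c(nodes, frontier)
    nxt <- unique(unlist(parents_of[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, nodes)
    if (length(nodes) > length(unique(c(child, parent))) + 1) break # safety
  }
  nodes <- unique(nodes)

  keep <- child %in% nodes & parent %in% nodes
  dag_edges <- data.frame(child = child[keep], parent = parent[keep])

  # Kahn-style acyclicity check on the restricted edge set
  ec <- dag_edges$child; ep <- dag_edges$parent
  repeat {
    leaves <- setdiff(unique(c(ec, ep)), ep)   # nodes that are no parent
    if (!length(leaves)) break
    keep2 <- !(ec %in% leaves)
    ec <- ec[keep2]; ep <- ep[keep2]
  }
  if (length(ec)) {
    stop_ldapred("cycle detected in the ontology", "ontology_error")
  }
  children_of <- split(dag_edges$child, dag_edges$parent)

  # memoized downward recursion for contributions; detects cycles
  memo <- new.env(parent = emptyenv())
  state <- new.env(parent = emptyenv())
  contrib <- function(t) {
    if (t == disease) return(1)
    if (!is.null(memo[[t]])) return(memo[[t]])
    if (isTRUE(state[[t]])) {
      stop_ldapred("cycle detected in the ontology", "ontology_error")
    }
    state[[t]] <- TRUE
    kids <- children_of[[t]]
    if (is.null(kids) || !length(kids)) {
      stop_ldapred("cycle detected in the ontology", "ontology_error")
    }
    v <- gamma * max(vapply(unique(kids), contrib, 0))
    state[[t]] <- FALSE
    memo[[t]] <- v
    v
  }
  contributions <- vapply(nodes, contrib, 0)
  names(contributions) <- nodes

  structure(list(disease_id = disease, nodes = nodes, edges = dag_edges,
                 contributions = contributions, gamma = gamma),
            class = "disease_dag")
}

#' Semantic value of a disease DAG
#'
#' The sum of all semantic contributions in the DAG; at least 1 because
#' the disease itself always contributes 1.
#' @param dag a [build_disease_dag()] result.
#' @return numeric scalar `>= 1`.
#' @export
semantic_value <- function(dag) {
  if (!inherits(dag, "disease_dag") || !length(dag$contributions)) {
    stop_ldapred("empty or invalid disease DAG", "input_error")
  }
  sum(dag$contributions)
}

#' Disease-disease semantic similarity from ancestor overlap
#'
#' For two diseases the similarity is the sum, over shared DAG nodes, of
#' both contributions, normalized by the sum of the two semantic values.
#' Diseases whose DAGs overlap more (closer in the ontology) score
#' higher; a disease against itself scores exactly 1 and disjoint DAGs
#' score 0.
#'
#' @param dags list of `"disease_dag"` objects, all built with the same
#'   `gamma`; names default to their disease ids.
#' @return symmetric similarity matrix of kind `"semantic"` with unit
#'   diagonal.
#' @export
disease_semantic_similarity <- function(dags) {
  if (!length(dags)) stop_ldapred("need at least one DAG", "input_error")
  gammas <- vapply(dags, function(d) d$gamma, 0)
  if (max(gammas) - min(gammas) > 0) {
    stop_ldapred("all DAGs must share the same gamma", "input_error")
  }
  ids <- vapply(dags, function(d) d$disease_id, "")
  if (anyDuplicated(ids)) stop_ldapred("duplicate disease ids", "input_error")
  sv <- vapply(dags, semantic_value, 0)
  n <- length(dags)
  out <- matrix(0, n, n, dimnames = list(ids, ids))
  contribs <- lapply(dags, `[[`, "contributions")
  for (i in seq_len(n)) {
    ci <- contribs[[i]]
    for (j in i:n) {
      shared <- intersect(names(ci), names(contribs[[j]]))
      if (length(shared)) {
        out[i, j] <- out[j, i] <-
          sum(ci[shared] + contribs[[j]][shared]) / (sv[i] + sv[j])
      }
    }
  }
  similarity_matrix(out, kind = "semantic")
}

#' Build semantic similarity for a disease registry in one call
#'
#' Convenience wrapper: builds one DAG per disease (isolated terms allowed)
#' and returns their pairwise semantic similarity. With `ontology = NULL`
#' every DAG is a singleton and the result is the identity matrix.
#' @param disease_ids character vector of diseases.
#' @inheritParams build_disease_dag
#' @return similarity matrix of kind `"semantic"`.
#' @export
semantic_similarity_matrix <- function(disease_ids, ontology = NULL, gamma = 0.5) {
  if (is.null(ontology)) {
    ontology <- data.frame(child = character(), parent = character())
  }
  dags <- lapply(disease_ids, build_disease_dag, ontology = ontology, gamma = gamma)
  disease_semantic_similarity(dags)
}
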