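#' Specification of a synthetic benchmark dataset
#'
#' Describes a planted-structure bipartite dataset mirroring the scale
#' and sparsity of curated lncRNA-disease catalogues: by default 156
#' lncRNAs x 190 diseases split into 4 latent blocks with within-block
#' association density 0.04 and background density 0.0025, which yields
#' about 352 expected associations. The ontology side is a forest of one
#' random rooted DAG per block so that diseases of the same block share
#' ancestry.
#'
#' @param nl,nd numbers of lncRNAs and diseases.
#' @param n_blocks latent blocks planted in the matrix (and trees in the
#'   ontology forest).
#' @param density_in,density_out Bernoulli densities inside / outside
#'   blocks; `0 <= density_out < density_in <= 1`.
#' @param dag_depth maximum depth of each ontology tree.
#' @param branching maximum children per ontology node.
#' @param dag_extra_edge_prob probability that a node receives a second
#'   parent (turning the tree into a proper DAG).
#' @param seed master seed.
#' @return list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(nl = 156, nd = 190, n_blocks = 4,
                           density_in = 0.04, density_out = 0.0025,
                           dag_depth = 4, branching = 3,
                           dag_extra_edge_prob = 0.15, seed = 1) {
  if (!(density_out >= 0 && density_out < density_in && density_in <= 1)) {
    stop_ldapred("need 0 <= density_out < density_in <= 1", "input_error")
  }
  if (nl < n_blocks || nd < n_blocks) {
    stop_ldapred("nl and nd must be at least n_blocks", "input_error")
  }
  if (dag_depth < 1) stop_ldapred("dag_depth must be >= 1", "input_error")
  structure(list(nl = as.integer(nl), nd = as.integer(nd),
                 n_blocks = as.integer(n_blocks),
                 density_in = density_in, density_out = density_out,
                 dag_depth = as.integer(dag_depth),
                 branching = as.integer(branching),
                 dag_extra_edge_prob = dag_extra_edge_prob,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

synthetic_block_labels <- function(n, n_blocks) {
  as.integer(cut(seq_len(n), n_blocks, labels = FALSE))
}

#' Generate a random disease ontology forest
#'
#' Builds one rooted random-recursive tree per block over that block's
#' disease identifiers: each disease after the root picks a parent among
#' already placed diseases with depth below `dag_depth` and fewer than
#' `branching` children. With probability `dag_extra_edge_prob` a node
#' gains a second parent at strictly smaller depth, producing diamond
#' motifs while staying acyclic by construction (every edge points from
#' larger to strictly smaller depth).
#'
#' @param spec a [synthetic_spec()].
#' @param disease_ids optional identifiers (default `d001...`).
#' @return data frame of `child`, `parent` edges covering all diseases.
#' @export
generate_dag_forest <- function(spec, disease_ids = NULL) {
  nd <- spec$nd
  disease_ids <- disease_ids %||% sprintf("d%03d", seq_len(nd))
  blocks <- synthetic_block_labels(nd, spec$n_blocks)
  edges_c <- character(0); edges_p <- character(0)
  with_seed(derive_seed(spec$seed, 11L), {
    for (b in seq_len(spec$n_blocks)) {
      ids <- disease_ids[blocks == b]
      if (length(ids) < 2) next
      depth <- c(0L)                 # depth of placed nodes; ids[1] is root
      nkids <- c(0L)
      for (i in 2:length(ids)) {
        ok <- which(depth < spec$dag_depth & nkids < spec$branching)
        if (!length(ok)) ok <- which(depth < spec$dag_depth)
        if (!length(ok)) ok <- seq_along(depth)
        parent <- if (length(ok) == 1) ok else sample(ok, 1)
        edges_c <- c(edges_c, ids[i]); edges_p <- c(edges_p, ids[parent])
        depth[i] <- depth[parent] + 1L
        nkids[parent] <- nkids[parent] + 1L
        nkids[i] <- 0L
        extra <- which(depth[seq_len(i - 1)] < depth[i])
        extra <- setdiff(extra, parent)
        if (length(extra) && stats::runif(1) < spec$dag_extra_edge_prob) {
          p2 <- if (length(extra) == 1) extra else sample(extra, 1)
          edges_c <- c(edges_c, ids[i]); edges_p <- c(edges_p, ids[p2])
        }
      }
    }
  })
  data.frame(child = edges_c, parent = edges_p)
}

#' Generate a planted block-structured association matrix
#'
#' lncRNAs and diseases are partitioned into `n_blocks` aligned groups;
#' cell `(l, d)` is Bernoulli with probability `density_in` when the two
#' nodes share a block and `density_out` otherwise. The block labels are
#' returned as ground truth for recovery scoring.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `assoc` (an [association_matrix()]),
#'   `lncrna_blocks`, `disease_blocks`.
#' @export
generate_association_matrix <- function(spec) {
  nl <- spec$nl; nd <- spec$nd
  lb <- synthetic_block_labels(nl, spec$n_blocks)
  db <- synthetic_block_labels(nd, spec$n_blocks)
  P <- matrix(spec$density_out, nl, nd)
  P[outer(lb, db, "==")] <- spec$density_in
  if (all(P == 0)) {
    stop_ldapred("degenerate spec: expected matrix is all zero", "input_error")
  }
  vals <- with_seed(derive_seed(spec$seed, 7L),
                    matrix(stats::rbinom(nl * nd, 1, P), nl, nd))
  dimnames(vals) <- list(sprintf("l%03d", seq_len(nl)),
                         sprintf("d%03d", seq_len(nd)))
  list(assoc = association_matrix(vals), lncrna_blocks = lb,
       disease_blocks = db)
}

#' Mask known associations for held-out evaluation
#'
#' Either removes a uniform fraction of the positives, or zeroes entire
#' disease columns (`columns` mode) to exercise cold-start prediction.
#'
#' @param assoc an [association_matrix()].
#' @param fraction fraction of positives to remove, in (0, 1); ignored
#'   when `columns` is given.
#' @param seed RNG seed for the uniform draw.
#' @param columns disease identifiers whose whole columns are masked.
#' @return list with `train` (masked [association_matrix()]) and
#'   `heldout` (integer pair matrix of removed positives).
#' @export
mask_entries <- function(assoc, fraction = NULL, seed = 1, columns = NULL) {
  a <- unclass(assoc)
  if (!is.null(columns)) {
    j <- match(columns, colnames(a))
    if (anyNA(j)) stop_ldapred("unknown disease column(s)", "lookup_error")
    held <- which(a[, j, drop = FALSE] == 1, arr.ind = TRUE)
    held <- cbind(lncrna = held[, 1], disease = j[held[, 2]])
    a[, j] <- 0
  } else {
    if (is.null(fraction) || !(fraction > 0 && fraction < 1)) {
      stop_ldapred("fraction must lie in (0, 1)", "input_error")
    }
    pos <- which(a == 1, arr.ind = TRUE)
    n_rm <- round(fraction * nrow(pos))
    if (n_rm >= nrow(pos)) {
      stop_ldapred("masking would remove every positive", "input_error")
    }
    sel <- with_seed(seed, sample.int(nrow(pos), n_rm))
    held <- pos[sel, , drop = FALSE]
    colnames(held) <- c("lncrna", "disease")
    a[held] <- 0
  }
  if (sum(a) == 0) {
    stop_ldapred("masking removed every positive", "input_error")
  }
  list(train = association_matrix(a), heldout = held)
}
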