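#' Build the neighborhood index of the heterogeneous graph
#'
#' Defines the graph the attention layer operates on. A disease's
#' neighbors are the lncRNAs it is associated with plus every disease
#' with positive integrated similarity; lncRNA neighborhoods are
#' symmetric. Every node receives a self-loop so no neighborhood is ever
#' empty (the softmax normalization requires at least one neighbor).
#'
#' @param assoc an [association_matrix()] (`nl x nd`).
#' @param ds_i integrated disease similarity (`nd x nd`).
#' @param fs_i integrated lncRNA similarity (`nl x nl`).
#' @return object of class `"neighbor_index"`: list with the logical
#'   adjacency matrix (`(nd+nl) x (nd+nl)`, diseases first), node ids and
#'   the two block sizes.
#' @export
build_neighbor_index <- function(assoc, ds_i, fs_i) {
  nd <- ncol(assoc); nl <- nrow(assoc)
  stopifnot(nrow(ds_i) == nd, nrow(fs_i) == nl)
  a_dd <- unclass(ds_i) > 0
  a_ll <- unclass(fs_i) > 0
  a_dl <- t(unclass(assoc)) == 1            # nd x nl
  adj <- rbind(cbind(a_dd, a_dl),
               cbind(t(a_dl), a_ll))
  diag(adj) <- TRUE
  ids <- c(colnames(assoc), rownames(assoc))
  dimnames(adj) <- list(ids, ids)
  structure(list(adjacency = adj, node_ids = ids, nd = nd, nl = nl),
            class = "neighbor_index")
}

#' @export
print.neighbor_index <- function(x, ...) {
  cat(sprintf("neighbor index: %d diseases + %d lncRNAs, mean degree %.1f\n",
              x$nd, x$nl, mean(rowSums(x$adjacency))))
  invisible(x)
}

#' Initialize the parameters of one attention head
#'
#' Glorot-uniform initialization. Each head holds the diagonal feature
#' weighting `W` (length d), the attention vector `a` (length 2d), and
#' the two per-branch projection matrices to `k` neurons: `W1_sum`
#' (`d x k`, applied to the sum of the node and neighborhood features)
#' and `W1_cat` (`2d x k`, applied to their concatenation).
#'
#' @param d node feature dimension.
#' @param k neurons per head.
#' @return list with elements `W`, `a`, `W1_sum`, `W1_cat`.
#' @keywords internal
init_head_params <- function(d, k) {
  glorot <- function(fin, fout, n = fin * fout) {
    lim <- sqrt(6 / (fin + fout))
    stats::runif(n, -lim, lim)
  }
  list(W = glorot(d, 1, d),
       a = glorot(2 * d, 1, 2 * d),
       W1_sum = matrix(glorot(d, k), d, k),
       W1_cat = matrix(glorot(2 * d, k), 2 * d, k))
}

#' Raw attention score between two nodes
#'
#' Single-layer attention: the features are weighted elementwise by `W`,
#' the weighted pair is concatenated, projected onto the attention
#' vector `a`, and passed through a LeakyReLU. The score is asymmetric in
#' (i, j) by construction of the concatenation.
#'
#' @param h_i,h_j node feature vectors (length d).
#' @param params head parameters, see [init_head_params()].
#' @param slope LeakyReLU negative slope.
#' @return numeric scalar.
#' @export
attention_scores <- function(h_i, h_j, params, slope = 0.2) {
  d <- length(params$W)
  if (length(h_i) != d || length(h_j) != d || length(params$a) != 2 * d) {
    stop_ldapred("feature/parameter shapes do not conform", "shape_error")
  }
  z <- sum(params$a[seq_len(d)] * (params$W * h_i)) +
       sum(params$a[d + seq_len(d)] * (params$W * h_j))
  unname(leaky_relu(z, slope))
}

#' Softmax normalization of attention scores over a neighborhood
#'
#' @param scores numeric vector of raw scores over the neighbors of one
#'   node (must be non-empty).
#' @return coefficients in `(0, 1]` summing to 1.
#' @export
normalize_attention <- function(scores) {
  if (!length(scores)) {
    stop_ldapred("empty neighbor set (self-loops should prevent this)",
                 "input_error")
  }
  e <- exp(scores - max(scores))
  e / sum(e)
}

#' Convex aggregation of neighbor features
#'
#' @param alpha attention coefficients (one per neighbor, summing to 1).
#' @param features matrix of neighbor feature vectors, one per row.
#' @return aggregated feature vector; lies in the convex hull of the
#'   rows of `features`.
#' @export
aggregate_neighbors <- function(alpha, features) {
  features <- rbind(features)
  if (length(alpha) != nrow(features)) {
    stop_ldapred("one coefficient per neighbor required", "shape_error")
  }
  drop(crossprod(features, alpha))
}

#' Multiple-operator aggregation of a node and its neighborhood feature
#'
#' The head combiner: a sum branch `LeakyReLU((h_i + h_Ni) W1_sum)`, a
#' concatenation branch `LeakyReLU((h_i || h_Ni) W1_cat)`, and their
#' element-wise product, all added together. With `variant =
#' "plain_gat"` only the concatenation branch is kept (standard
#' multi-head attention head).
#'
#' @param h_i node feature vector (length d).
#' @param h_Ni aggregated neighborhood feature (length d).
#' @param params head parameters.
#' @param slope LeakyReLU negative slope.
#' @param variant `"full"` or `"plain_gat"`.
#' @return vector of length `k` (the head's neurons).
#' @export
multi_operator_aggregate <- function(h_i, h_Ni, params, slope = 0.2,
                                     variant = "full") {
  d <- length(h_i)
  if (length(h_Ni) != d || nrow(params$W1_sum) != d ||
      nrow(params$W1_cat) != 2 * d) {
    stop_ldapred("feature/parameter shapes do not conform", "shape_error")
  }
  b_cat <- leaky_relu(drop(crossprod(params$W1_cat, c(h_i, h_Ni))), slope)
  if (identical(variant, "plain_gat")) return(b_cat)
  b_sum <- leaky_relu(drop(crossprod(params$W1_sum, h_i + h_Ni)), slope)
  b_sum + b_cat + b_sum * b_cat
}

# ---- vectorized forward pass over all nodes -------------------------------

# One head, all nodes at once. Returns the head output (N x k) plus every
# intermediate needed for the backward pass.
gat_head_forward <- function(X, mask_neg, p, slope, variant) {
  N <- nrow(X)
  XW <- sweep(X, 2L, p$W, "*")
  d <- ncol(X)
  a1 <- p$a[seq_len(d)]; a2 <- p$a[d + seq_len(d)]
  u <- drop(XW %*% a1)
  v <- drop(XW %*% a2)
  Zpre <- matrix(u, N, N) + matrix(v, N, N, byrow = TRUE)
  E <- leaky_relu(Zpre, slope) + mask_neg     # -Inf off-neighborhood
  rowmax <- E[cbind(seq_len(N), max.col(E, ties.method = "first"))]
  A <- exp(E - rowmax)
  alpha <- A / rowSums(A)
  HN <- alpha %*% X
  S <- X + HN
  C <- cbind(X, HN)
  P2 <- C %*% p$W1_cat
  B2 <- leaky_relu(P2, slope)
  if (identical(variant, "plain_gat")) {
    Mk <- B2
    P1 <- B1 <- NULL
  } else {
    P1 <- S %*% p$W1_sum
    B1 <- leaky_relu(P1, slope)
    Mk <- B1 + B2 + B1 * B2
  }
  list(Mk = Mk, XW = XW, u = u, v = v, Zpre = Zpre, alpha = alpha,
       HN = HN, S = S, C = C, P1 = P1, P2 = P2, B1 = B1, B2 = B2)
}

# Full multi-head forward. `mask` is the logical adjacency.
gat_forward <- function(X, mask, params, slope, variant) {
  mask_neg <- ifelse(mask, 0, -Inf)
  caches <- lapply(params$heads, function(p)
    gat_head_forward(X, mask_neg, p, slope, variant))
  M <- do.call(cbind, lapply(caches, `[[`, "Mk"))
  list(M = M, caches = caches)
}

# Backward through one head given dMk (N x k); accumulates parameter
# gradients and returns them (gradient w.r.t. X is not needed: X is data).
gat_head_backward <- function(X, p, cache, dMk, slope, variant) {
  d <- ncol(X)
  if (identical(variant, "plain_gat")) {
    dB2 <- dMk
    dP2 <- dB2 * leaky_relu_grad(cache$P2, slope)
    gW1_cat <- crossprod(cache$C, dP2)
    gW1_sum <- matrix(0, nrow(p$W1_sum), ncol(p$W1_sum))
    dC <- tcrossprod(dP2, p$W1_cat)
    dHN <- dC[, d + seq_len(d), drop = FALSE]
  } else {
    dB1 <- dMk * (1 + cache$B2)
    dB2 <- dMk * (1 + cache$B1)
    dP1 <- dB1 * leaky_relu_grad(cache$P1, slope)
    dP2 <- dB2 * leaky_relu_grad(cache$P2, slope)
    gW1_sum <- crossprod(cache$S, dP1)
    gW1_cat <- crossprod(cache$C, dP2)
    dS <- tcrossprod(dP1, p$W1_sum)
    dC <- tcrossprod(dP2, p$W1_cat)
    dHN <- dS + dC[, d + seq_len(d), drop = FALSE]
  }
  alpha <- cache$alpha
  dalpha <- tcrossprod(dHN, X)
  rowdot <- rowSums(alpha * dalpha)
  dE <- alpha * sweep(dalpha, 1L, rowdot, "-")
  dZ <- dE * leaky_relu_grad(cache$Zpre, slope)
  du <- rowSums(dZ)
  dv <- colSums(dZ)
  a1 <- p$a[seq_len(d)]; a2 <- p$a[d + seq_len(d)]
  ga <- c(drop(crossprod(cache$XW, du)), drop(crossprod(cache$XW, dv)))
  dXW <- outer(du, a1) + outer(dv, a2)
  gW <- colSums(dXW * X)
  list(W = gW, a = ga, W1_sum = gW1_sum, W1_cat = gW1_cat)
}

#' Encode all nodes with the multi-head attention layer
#'
#' Runs the forward pass of the encoder: per head, attention coefficients
#' over each neighborhood, convex aggregation of neighbor features, and
#' the multiple-operator combiner; the per-head outputs are concatenated
#' along the feature axis, giving `n_heads * neurons` embedding
#' dimensions.
#'
#' @param X heterogeneous feature matrix from
#'   [assemble_feature_matrix()].
#' @param neighbor_index a [build_neighbor_index()] result.
#' @param params model parameters (see [init_model_params()]); only the
#'   head parameters are used.
#' @param config an [default_config()] list (slope, variant).
#' @return object of class `"node_embeddings"`: list with the full
#'   embedding matrix `M`, its disease block `Md` (first `nd` rows) and
#'   lncRNA block `Ml` (last `nl` rows).
#' @export
encode_nodes <- function(X, neighbor_index, params, config = default_config()) {
  fw <- gat_forward(unclass(X), neighbor_index$adjacency, params,
                    config$leaky_slope, config$variant)
  nd <- neighbor_index$nd; nl <- neighbor_index$nl
  M <- fw$M
  rownames(M) <- neighbor_index$node_ids
  structure(list(M = M,
                 Md = M[seq_len(nd), , drop = FALSE],
                 Ml = M[nd + seq_len(nl), , drop = FALSE]),
            class = "node_embeddings")
}
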