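#' Initialize all trainable parameters
#'
#' Glorot-uniform initialization of the attention heads and of the two
#' inductive-completion projection matrices `Pd`, `Pl` (embedding
#' dimension `n_heads * neurons` down to rank `r`). For the
#' `"plain_mc"` ablation the model instead holds directly learned
#' full-rank factor matrices `U` (`nl x r`) and `V` (`nd x r`) and no
#' encoder.
#'
#' @param nd,nl numbers of diseases and lncRNAs.
#' @param config an [default_config()] list.
#' @param seed RNG seed for the draw; defaults to `config$seed`.
#' @return list of class `"model_params"`.
#' @export
init_model_params <- function(nd, nl, config = default_config(),
                              seed = config$seed) {
  d <- nd + nl
  k <- config$neurons
  emb <- config$n_heads * k
  r <- config$rank %||% emb
  with_seed(seed, {
    if (identical(config$variant, "plain_mc")) {
      r_mc <- min(nl, nd)  # plain matrix completion: full-rank factors
      lim <- sqrt(6 / (nl + r_mc))
      U <- matrix(stats::runif(nl * r_mc, -lim, lim), nl, r_mc)
      lim <- sqrt(6 / (nd + r_mc))
      V <- matrix(stats::runif(nd * r_mc, -lim, lim), nd, r_mc)
      params <- list(U = U, V = V)
    } else {
      heads <- lapply(seq_len(config$n_heads), function(h) init_head_params(d, k))
      lim <- sqrt(6 / (emb + r))
      Pd <- matrix(stats::runif(emb * r, -lim, lim), emb, r)
      Pl <- matrix(stats::runif(emb * r, -lim, lim), emb, r)
      params <- list(heads = heads, Pd = Pd, Pl = Pl)
    }
    structure(params, class = "model_params", variant = config$variant,
              nd = nd, nl = nl)
  })
}

#' Reconstruct the association matrix from node embeddings
#'
#' Inductive matrix completion readout: the lncRNA and disease embedding
#' blocks are projected to rank `r` and their outer product yields the
#' raw `nl x nd` reconstruction; a sigmoid squashes it into `[0, 1]` for
#' reporting and ranking (monotone, so rankings are unchanged). Training
#' minimizes the Frobenius error of the raw linear reconstruction.
#' Because the parameters live in feature space (not indexed by
#' individual nodes), rows/columns with no observed association still
#' receive informative scores.
#'
#' @param embeddings a [encode_nodes()] result.
#' @param params a [init_model_params()] result (uses `Pd`, `Pl`).
#' @param raw return the raw linear reconstruction instead of the
#'   sigmoid-squashed scores.
#' @return matrix of scores, lncRNAs x diseases; in `[0, 1]` unless
#'   `raw = TRUE`.
#' @export
reconstruct_associations <- function(embeddings, params, raw = FALSE) {
  if (any(!is.finite(embeddings$M))) {
    stop_ldapred("non-finite node embeddings", "input_error")
  }
  Ud <- embeddings$Md %*% params$Pd
  Ul <- embeddings$Ml %*% params$Pl
  scores <- tcrossprod(Ul, Ud)
  if (!raw) scores <- sigmoid(scores)
  dimnames(scores) <- list(rownames(embeddings$Ml), rownames(embeddings$Md))
  scores
}

#' Reconstruction loss
#'
#' Squared Frobenius error between the (train-masked) association matrix
#' and its reconstruction over every entry, plus `lambda` times the
#' squared Frobenius norm of all trainable projection weights (the
#' inductive projections and the per-head branch projections). During
#' training the reconstruction entering this loss is the raw linear
#' low-rank product (see [reconstruct_associations()]).
#'
#' @param assoc_train binary `nl x nd` training matrix (held-out
#'   positives zeroed).
#' @param recon reconstructed matrix of the same shape.
#' @param params model parameters whose projection weights enter the
#'   penalty; `NULL` for a pure data term.
#' @param lambda equilibrium factor, default 1.
#' @return non-negative scalar.
#' @export
association_loss <- function(assoc_train, recon, params = NULL, lambda = 1) {
  if (!identical(dim(assoc_train), dim(recon))) {
    stop_ldapred("association and reconstruction shapes differ", "shape_error")
  }
  data_term <- sum((unclass(assoc_train) - recon)^2)
  data_term + lambda * projection_penalty(params)
}

projection_penalty <- function(params) {
  if (is.null(params)) return(0)
  if (identical(attr(params, "variant"), "plain_mc")) {
    return(sum(params$U^2) + sum(params$V^2))
  }
  pen <- sum(params$Pd^2) + sum(params$Pl^2)
  for (h in params$heads) {
    pen <- pen + sum(h$W1_sum^2) + sum(h$W1_cat^2)
  }
  pen
}

# ---- full forward/backward pass -------------------------------------------
# Returns loss, score matrix, and gradients in the same nested layout as
# `params`. A is the nl x nd training matrix; X the feature matrix; mask
# the adjacency. Regularization gradients are included.
forward_backward <- function(A, X, mask, params, config) {
  nd <- attr(params, "nd"); nl <- attr(params, "nl")
  lambda <- config$lambda
  if (identical(config$variant, "plain_mc")) {
    G <- tcrossprod(params$U, params$V)
    diff <- G - A
    loss <- sum(diff^2) + lambda * (sum(params$U^2) + sum(params$V^2))
    dG <- 2 * diff
    grads <- list(U = dG %*% params$V + 2 * lambda * params$U,
                  V = crossprod(dG, params$U) + 2 * lambda * params$V)
    return(list(loss = loss, scores = sigmoid(G), grads = grads))
  }
  slope <- config$leaky_slope
  fw <- gat_forward(X, mask, params, slope, config$variant)
  M <- fw$M
  Md <- M[seq_len(nd), , drop = FALSE]
  Ml <- M[nd + seq_len(nl), , drop = FALSE]
  Ud <- Md %*% params$Pd
  Ul <- Ml %*% params$Pl
  G <- tcrossprod(Ul, Ud)
  diff <- G - A
  loss <- sum(diff^2) + lambda * projection_penalty(params)

  scores <- sigmoid(G)
  dG <- 2 * diff
  dUl <- dG %*% Ud
  dUd <- crossprod(dG, Ul)
  gPl <- crossprod(Ml, dUl) + 2 * lambda * params$Pl
  gPd <- crossprod(Md, dUd) + 2 * lambda * params$Pd
  dMl <- tcrossprod(dUl, params$Pl)
  dMd <- tcrossprod(dUd, params$Pd)
  dM <- rbind(dMd, dMl)

  k <- config$neurons
  head_grads <- vector("list", config$n_heads)
  for (h in seq_len(config$n_heads)) {
    idx <- (h - 1L) * k + seq_len(k)
    g <- gat_head_backward(X, params$heads[[h]], fw$caches[[h]],
                           dM[, idx, drop = FALSE], slope, config$variant)
    g$W1_sum <- g$W1_sum + 2 * lambda * params$heads[[h]]$W1_sum
    g$W1_cat <- g$W1_cat + 2 * lambda * params$heads[[h]]$W1_cat
    head_grads[[h]] <- g
  }
  dimnames(scores) <- dimnames(A)
  list(loss = loss, scores = scores,
       grads = list(heads = head_grads, Pd = gPd, Pl = gPl))
}
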