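# Recursive elementwise map over identically shaped nested parameter lists.
param_map <- function(f, ...) {
  ps <- list(...)
  if (is.list(ps[[1]])) {
    out <- lapply(seq_along(ps[[1]]), function(i) {
      do.call(param_map, c(list(f), lapply(ps, `[[`, i)))
    })
    names(out) <- names(ps[[1]])
    out
  } else {
    do.call(f, ps)
  }
}

adam_init <- function(params) {
  zeros <- param_map(function(x) x * 0, unclass_params(params))
  list(m = zeros, v = zeros, t = 0L)
}

unclass_params <- function(p) {
  attrs <- attributes(p)
  p <- unclass(p)
  attributes(p) <- attrs[c("names")]
  p
}

# One AdamW step (decoupled weight decay) over the nested parameter list.
adam_step <- function(params, grads, state, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- param_map(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- param_map(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  attrs <- attributes(params)
  new <- param_map(function(p, m, v) {
    p - lr * ((m / c1) / (sqrt(v / c2) + eps) + weight_decay * p)
  }, unclass_params(params), state$m, state$v)
  attributes(new) <- attrs
  list(params = new, state = state)
}

#' Build every similarity network and the feature matrix for a dataset
#'
#' Convenience wrapper running the whole similarity stage: disease
#' semantic similarity (from the ontology, or the identity when no
#' ontology is available — every disease is then its own singleton DAG),
#' lncRNA functional similarity, both Gaussian interaction-profile
#' kernels, the two integration rules, the heterogeneous feature matrix
#' and the neighborhood index. Under the `"no_gaussian"` ablation both
#' kernels are zeroed before integration.
#'
#' @param assoc an [association_matrix()].
#' @param ontology optional ontology edge data frame (see
#'   [read_ontology()]).
#' @param config an [default_config()] list.
#' @param disease_sim optional precomputed semantic similarity (used by
#'   cross-validation to avoid rebuilding DAGs per fold).
#' @return list with components `ds`, `fs`, `gd`, `gl`, `ds_i`, `fs_i`,
#'   `X`, `neighbor_index`.
#' @export
build_similarity_stack <- function(assoc, ontology = NULL,
                                   config = default_config(),
                                   disease_sim = NULL) {
  ds <- disease_sim %||%
    semantic_similarity_matrix(colnames(assoc), ontology,
                               gamma = config$semantic_gamma)
  ds <- similarity_matrix(ds[colnames(assoc), colnames(assoc)],
                          kind = "semantic")
  fs <- lncrna_functional_similarity(assoc, ds)
  if (identical(config$variant, "no_gaussian")) {
    zd <- matrix(0, ncol(assoc), ncol(assoc),
                 dimnames = list(colnames(assoc), colnames(assoc)))
    zl <- matrix(0, nrow(assoc), nrow(assoc),
                 dimnames = list(rownames(assoc), rownames(assoc)))
    gd <- similarity_matrix(zd, kind = "gaussian")
    gl <- similarity_matrix(zl, kind = "gaussian")
  } else {
    gd <- gip_similarity(assoc, "disease")
    gl <- gip_similarity(assoc, "lncrna")
  }
  ds_i <- integrate_disease_similarity(ds, gd,
                                       average = isTRUE(config$integrate_average))
  fs_i <- integrate_lncrna_similarity(fs, gl)
  X <- assemble_feature_matrix(ds_i, fs_i)
  nbr <- build_neighbor_index(assoc, ds_i, fs_i)
  list(ds = ds, fs = fs, gd = gd, gl = gl, ds_i = ds_i, fs_i = fs_i,
       X = X, neighbor_index = nbr)
}

#' Train the association prediction model
#'
#' End-to-end training: the similarity stack is built from the training
#' association matrix, node features are encoded by the multi-head
#' attention layer, the association matrix is reconstructed by inductive
#' matrix completion, and all parameters (attention heads and
#' projections) are optimized jointly with Adam (decoupled weight decay)
#' on the whole-matrix squared reconstruction error plus an L2 penalty on
#' the projection weights. Unknown pairs act as weak negatives.
#'
#' With a fixed `config$seed` the loss trajectory and fitted parameters
#' are exactly reproducible. Training aborts with a diagnostic if the
#' loss becomes non-finite.
#'
#' @param assoc training [association_matrix()] (held-out positives
#'   already zeroed, if any).
#' @param ontology optional ontology edge data frame for disease
#'   semantic similarity.
#' @param config an [default_config()] list.
#' @param disease_sim optional precomputed semantic similarity matrix.
#' @return object of class `"lda_fit"`: list with fitted `params`,
#'   per-epoch `losses`, final `scores` (`nl x nd`, in `[0, 1]`),
#'   `embeddings`, the similarity `stack`, and the `config` used.
#' @examples
#' \donttest{
#' syn <- generate_association_matrix(synthetic_spec(nl = 20, nd = 15,
#'   n_blocks = 2, density_in = 0.4, density_out = 0.02, seed = 1))
#' fit <- train_model(syn$assoc, config = default_config(epochs = 20,
#'   n_heads = 2, neurons = 4, seed = 1))
#' range(fit$scores)
#' }
#' @export
train_model <- function(assoc, ontology = NULL, config = default_config(),
                        disease_sim = NULL) {
  if (config$epochs < 1) {
    stop_ldapred("epochs must be >= 1", "input_error")
  }
  stack <- build_similarity_stack(assoc, ontology, config, disease_sim)
  nd <- ncol(assoc); nl <- nrow(assoc)
  params <- init_model_params(nd, nl, config, seed = config$seed)
  A <- unclass(assoc)
  X <- unclass(stack$X)
  mask <- stack$neighbor_index$adjacency

  losses <- numeric(0)
  if (isTRUE(config$train)) {
    use_cpp <- !identical(config$variant, "plain_mc") &&
      identical(config$engine, "cpp")
    if (use_cpp) {
      res <- .train_core_cpp(A, X, mask + 0L, params$heads, params$Pd,
                             params$Pl, nd, nl, config$leaky_slope,
                             config$lambda, config$lr, config$weight_decay,
                             config$epochs,
                             identical(config$variant, "plain_gat"))
      attrs <- attributes(params)
      params <- list(
        heads = lapply(res$heads, function(h) {
          list(W = drop(h$W), a = drop(h$a),
               W1_sum = h$W1_sum, W1_cat = h$W1_cat)
        }),
        Pd = res$Pd, Pl = res$Pl)
      attrs$names <- names(params)
      attributes(params) <- attrs
      losses <- drop(res$losses)
    } else {
      state <- adam_init(params)
      losses <- numeric(config$epochs)
      for (epoch in seq_len(config$epochs)) {
        fb <- forward_backward(A, X, mask, params, config)
        if (!is.finite(fb$loss)) {
          stop_ldapred(sprintf("training diverged at epoch %d (non-finite loss)",
                               epoch), "divergence_error")
        }
        losses[epoch] <- fb$loss
        upd <- adam_step(params, fb$grads, state, config$lr, config$weight_decay)
        params <- upd$params
        state <- upd$state
      }
    }
  }

  if (identical(config$variant, "plain_mc")) {
    scores <- sigmoid(tcrossprod(params$U, params$V))
    dimnames(scores) <- list(rownames(assoc), colnames(assoc))
    embeddings <- NULL
  } else {
    embeddings <- encode_nodes(stack$X, stack$neighbor_index, params, config)
    scores <- reconstruct_associations(embeddings, params)
  }

  structure(list(params = params, losses = losses, scores = scores,
                 embeddings = embeddings, stack = stack, config = config,
                 lncrna_ids = rownames(assoc), disease_ids = colnames(assoc)),
            class = "lda_fit")
}

#' @export
print.lda_fit <- function(x, ...) {
  cat(sprintf("association model fit (%s variant): %d lncRNAs x %d diseases\n",
              x$config$variant, length(x$lncrna_ids), length(x$disease_ids)))
  if (length(x$losses)) {
    cat(sprintf("  %d epochs, loss %.4f -> %.4f\n", length(x$losses),
                x$losses[1], x$losses[length(x$losses)]))
  } else {
    cat("  untrained (frozen random parameters)\n")
  }
  invisible(x)
}

#' Predicted association scores
#' @param object an `"lda_fit"`.
#' @param ... unused.
#' @return `nl x nd` matrix of scores in `[0, 1]`.
#' @export
predict.lda_fit <- function(object, ...) {
  object$scores
}

#' Rank candidate lncRNAs for a disease
#'
#' Sorts lncRNAs by predicted score for the given disease, in descending
#' order; ties are broken by lexicographic lncRNA identifier. Known
#' positives can be excluded so only novel candidates remain.
#'
#' @param scores score matrix (lncRNAs x diseases) or an `"lda_fit"`.
#' @param disease_id target disease identifier.
#' @param assoc association matrix of known positives (required when
#'   `exclude_known = TRUE` and `scores` is a bare matrix).
#' @param top keep only the first `top` candidates (`NULL` = all).
#' @param exclude_known drop lncRNAs already associated with the disease.
#' @return data frame with columns `rank`, `lncrna_id`, `score`.
#' @export
rank_candidates <- function(scores, disease_id, assoc = NULL, top = NULL,
                            exclude_known = TRUE) {
  if (inherits(scores, "lda_fit")) {
    fit <- scores
    scores <- fit$scores
    assoc <- assoc %||% NULL
  }
  if (!disease_id %in% colnames(scores)) {
    stop_ldapred(paste0("unknown disease: ", disease_id), "lookup_error")
  }
  s <- scores[, disease_id]
  ids <- rownames(scores)
  if (exclude_known) {
    if (is.null(assoc)) {
      stop_ldapred("assoc is required to exclude known positives", "input_error")
    }
    known <- rownames(assoc)[assoc[, disease_id] == 1]
    keep <- !(ids %in% known)
    s <- s[keep]; ids <- ids[keep]
  }
  ord <- order(-s, ids, method = "radix")
  out <- data.frame(rank = seq_along(ord), lncrna_id = ids[ord],
                    score = unname(s[ord]))
  if (!is.null(top)) out <- utils::head(out, top)
  out
}
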