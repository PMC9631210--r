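#' Partition known associations into cross-validation folds
#'
#' Positives are shuffled and split into `k` near-equal groups. For each
#' fold an equally sized set of unknown pairs is drawn uniformly without
#' replacement (disjoint across folds and from all positives) to serve
#' as test negatives; all remaining unknowns stay available to training.
#'
#' @param assoc an [association_matrix()].
#' @param k number of folds (default 5).
#' @param seed RNG seed controlling both the partition and the negative
#'   draw.
#' @return list of `k` folds, each a list with integer pair matrices
#'   (`lncrna`, `disease` columns): `train_pos`, `test_pos`, `test_neg`.
#' @export
make_folds <- function(assoc, k = 5, seed = 1) {
  k <- as.integer(k)
  pos <- which(unclass(assoc) == 1, arr.ind = TRUE)
  colnames(pos) <- c("lncrna", "disease")
  npos <- nrow(pos)
  if (k < 2 || npos < k) {
    stop_ldapred("need at least k positives and k >= 2", "input_error")
  }
  unk <- which(unclass(assoc) == 0)
  if (length(unk) < npos) {
    stop_ldapred("fewer unknown pairs than positives; cannot sample negatives",
                 "input_error")
  }
  with_seed(seed, {
    grp <- sample(rep_len(seq_len(k), npos))  # balanced random groups
    neg_lin <- sample(unk, npos)              # disjoint across folds
  })
  neg <- arrayInd(neg_lin, dim(assoc))
  colnames(neg) <- c("lncrna", "disease")
  lapply(seq_len(k), function(f) {
    test_idx <- which(grp == f)
    neg_idx <- which(rep_len(seq_len(k), npos) == f)
    list(fold_id = f,
         train_pos = pos[grp != f, , drop = FALSE],
         test_pos = pos[test_idx, , drop = FALSE],
         test_neg = neg[neg_idx, , drop = FALSE])
  })
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic: the probability that a random
#' positive outranks a random negative, with ties counted one half
#' (implemented through midranks).
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1), both classes present.
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))  # 0.75
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) {
    stop_ldapred("both classes must be present", "input_error")
  }
  r <- rank(scores)  # average ranks implement the half-count tie rule
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve
#'
#' Step-wise (non-interpolated) area from a threshold sweep over the
#' distinct score values: at each threshold the precision is weighted by
#' the recall increment. Tied scores enter or leave the positive
#' prediction set together. No linear interpolation between operating
#' points is applied, so the value is directly comparable to
#' average-precision style summaries.
#'
#' @inheritParams roc_auc
#' @return AUPR in `(0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  np <- sum(labels == 1)
  if (np == 0) stop_ldapred("at least one positive required", "input_error")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  tp <- cumsum(l); fp <- cumsum(1 - l)
  last <- which(c(diff(s) != 0, TRUE))   # last index of each tie group
  prec <- tp[last] / (tp[last] + fp[last])
  rec <- tp[last] / np
  sum(diff(c(0, rec)) * prec)
}

#' ROC and PR curve points
#' @inheritParams roc_auc
#' @return data frame with columns `threshold`, `fpr`, `tpr`,
#'   `precision`, `recall`.
#' @export
prediction_curves <- function(scores, labels) {
  labels <- as.integer(labels)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  tp <- cumsum(l); fp <- cumsum(1 - l)
  last <- which(c(diff(s) != 0, TRUE))
  data.frame(threshold = s[last],
             fpr = fp[last] / max(nn, 1),
             tpr = tp[last] / max(np, 1),
             precision = tp[last] / (tp[last] + fp[last]),
             recall = tp[last] / max(np, 1))
}

#' Repeated cross-validated evaluation
#'
#' For every repeat the positives are re-partitioned into `k` folds and
#' fresh test negatives are drawn. Per fold, the model is trained on the
#' association matrix with the fold's test positives zeroed (all unknown
#' pairs remain weak training negatives), and the held-out positives
#' plus sampled negatives are scored. AUC and AUPR are averaged over
#' folds and repeats. Fully deterministic given the master seed.
#'
#' @param assoc an [association_matrix()].
#' @param config an [default_config()] list (`folds`, `repeats`, model
#'   hyperparameters, master `seed`).
#' @param ontology optional ontology edge data frame; semantic similarity
#'   is computed once and shared across folds.
#' @param repeats,seed optional overrides of `config$repeats` /
#'   `config$seed`.
#' @return object of class `"cv_result"`: list with mean `auc`, `aupr`,
#'   a per-fold data frame `folds`, curve points (when
#'   `config$keep_curves`), and the protocol description.
#' @export
run_cv <- function(assoc, config = default_config(), ontology = NULL,
                   repeats = config$repeats, seed = config$seed) {
  ds <- semantic_similarity_matrix(colnames(assoc), ontology,
                                   gamma = config$semantic_gamma)
  rows <- list()
  curves <- list()
  for (rep_i in seq_len(repeats)) {
    folds <- make_folds(assoc, config$folds, seed = derive_seed(seed, rep_i))
    for (f in seq_along(folds)) {
      fold <- folds[[f]]
      a_train <- unclass(assoc)
      a_train[fold$test_pos] <- 0
      a_train <- association_matrix(a_train)
      cfg <- config
      cfg$seed <- derive_seed(seed, rep_i, f)
      fit <- train_model(a_train, config = cfg, disease_sim = ds)
      sc <- fit$scores
      test <- rbind(fold$test_pos, fold$test_neg)
      lab <- rep(c(1L, 0L), c(nrow(fold$test_pos), nrow(fold$test_neg)))
      s <- sc[test]
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_id = rep_i, fold_id = f,
        auc = roc_auc(s, lab), aupr = pr_auc(s, lab),
        n_test_pos = nrow(fold$test_pos))
      if (isTRUE(config$keep_curves)) {
        curves[[length(curves) + 1L]] <- cbind(
          data.frame(repeat_id = rep_i, fold_id = f),
          prediction_curves(s, lab))
      }
    }
  }
  folds_df <- do.call(rbind, rows)
  structure(list(auc = mean(folds_df$auc), aupr = mean(folds_df$aupr),
                 folds = folds_df,
                 curves = if (length(curves)) do.call(rbind, curves),
                 repeats = repeats, k = config$folds,
                 variant = config$variant, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation, %d repeat(s), variant '%s'\n",
              x$k, x$repeats, x$variant))
  cat(sprintf("  mean AUC  = %.4f\n  mean AUPR = %.4f\n", x$auc, x$aupr))
  invisible(x)
}

#' Cross-validated ablation experiment
#'
#' Runs [run_cv()] under one of the architecture switches:
#' `"no_gaussian"` drops both interaction-profile kernels before
#' integration, `"plain_gat"` keeps only the concatenation branch of the
#' head combiner (standard multi-head attention), `"plain_mc"` replaces
#' the inductive projections by directly learned full-rank factor
#' matrices, and `"full"` is the complete model.
#'
#' @inheritParams run_cv
#' @param variant ablation switch, see Details.
#' @return a `"cv_result"`.
#' @export
run_ablation <- function(assoc, variant = c("full", "no_gaussian",
                                            "plain_gat", "plain_mc"),
                         config = default_config(), ontology = NULL,
                         repeats = config$repeats, seed = config$seed) {
  variant <- match.arg(variant)
  config$variant <- variant
  run_cv(assoc, config, ontology, repeats = repeats, seed = seed)
}
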