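# Independent brute-force oracles used to pin the implementation.

# Semantic contribution by exhaustive upward path enumeration:
# D(t) = max over paths disease -> ... -> t of gamma^length. Independent
# of the package's memoized downward recursion.
oracle_contributions <- function(disease, edges, gamma) {
  best <- new.env(parent = emptyenv())
  recurse <- function(node, w) {
    cur <- if (is.null(best[[node]])) -Inf else best[[node]]
    if (w <= cur) return(invisible())
    best[[node]] <- w
    for (p in edges$parent[edges$child == node]) recurse(p, w * gamma)
  }
  recurse(disease, 1)
  unlist(as.list(best))
}

oracle_semantic_similarity <- function(d1, d2, edges, gamma) {
  c1 <- oracle_contributions(d1, edges, gamma)
  c2 <- oracle_contributions(d2, edges, gamma)
  shared <- intersect(names(c1), names(c2))
  if (!length(shared)) return(0)
  sum(c1[shared] + c2[shared]) / (sum(c1) + sum(c2))
}

# random acyclic ontology: edges only from higher to lower index
random_ontology <- function(n_nodes, edge_prob = 0.4) {
  ids <- paste0("t", seq_len(n_nodes))
  ch <- character(0); pa <- character(0)
  for (i in seq_len(n_nodes)[-1]) {
    parents <- which(stats::runif(i - 1) < edge_prob)
    if (!length(parents)) parents <- sample.int(i - 1, 1)
    ch <- c(ch, rep(ids[i], length(parents)))
    pa <- c(pa, ids[parents])
  }
  data.frame(child = ch, parent = pa)
}

# pairwise-comparison AUC with explicit half-count for ties
oracle_roc_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# step-wise PR area by exhaustive threshold enumeration
oracle_pr_auc <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0; area <- 0
  for (t in ths) {
    sel <- scores >= t
    prec <- sum(labels[sel]) / sum(sel)
    rec <- sum(labels[sel]) / sum(labels)
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

# scalar-loop reference for the multiple-operator head combiner
oracle_multi_operator <- function(h_i, h_Ni, W1_sum, W1_cat, slope) {
  d <- length(h_i); k <- ncol(W1_sum)
  lr <- function(x) if (x >= 0) x else slope * x
  out <- numeric(k)
  hc <- c(h_i, h_Ni)
  hs <- h_i + h_Ni
  for (j in seq_len(k)) {
    s1 <- 0
    for (i in seq_len(d)) s1 <- s1 + hs[i] * W1_sum[i, j]
    s2 <- 0
    for (i in seq_len(2 * d)) s2 <- s2 + hc[i] * W1_cat[i, j]
    b1 <- lr(s1); b2 <- lr(s2)
    out[j] <- b1 + b2 + b1 * b2
  }
  out
}
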