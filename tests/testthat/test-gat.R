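test_that("neighbor index mirrors associations, similarity support and self-loops", {
  a <- association_matrix(rbind(l1 = c(1, 0), l2 = c(0, 0)),
                          disease_ids = c("d1", "d2"))
  ids_d <- c("d1", "d2"); ids_l <- c("l1", "l2")
  ds_i <- similarity_matrix(matrix(c(1, 0, 0, 1), 2,
                                   dimnames = list(ids_d, ids_d)),
                            "integrated")
  fs_i <- similarity_matrix(matrix(c(1, 0, 0, 0), 2,
                                   dimnames = list(ids_l, ids_l)),
                            "integrated")
  nbr <- build_neighbor_index(a, ds_i, fs_i)
  adj <- nbr$adjacency
  expect_true(all(diag(adj)))                        # self-loops
  expect_true(adj["d1", "l1"] && adj["l1", "d1"])    # association edge
  expect_false(adj["d2", "l1"])
  # l2 has no association and no similarity support: only itself
  expect_equal(sum(adj["l2", ]), 1)
  # dense similarity: disease degree = (nd - 1) + assoc degree + self
  dsd <- similarity_matrix(matrix(c(1, .2, .2, 1), 2,
                                  dimnames = list(ids_d, ids_d)),
                           "integrated")
  nbr2 <- build_neighbor_index(a, dsd, fs_i)
  expect_equal(sum(nbr2$adjacency["d1", ]), (2 - 1) + 1 + 1)
})

test_that("attention scores: zero features give zero, asymmetric in general", {
  set.seed(3)
  p <- ldapred:::init_head_params(4, 2)
  expect_equal(attention_scores(rep(0, 4), rep(0, 4), p), 0)
  h1 <- runif(4); h2 <- runif(4)
  e12 <- attention_scores(h1, h2, p)
  e21 <- attention_scores(h2, h1, p)
  expect_false(isTRUE(all.equal(e12, e21)))
  expect_identical(e12, attention_scores(h1, h2, p))  # deterministic
  expect_error(attention_scores(h1, runif(3), p), class = "shape_error")
})

test_that("softmax normalization: single neighbor, equal scores, hand case", {
  expect_equal(normalize_attention(3.2), 1)
  expect_equal(normalize_attention(c(1, 1)), c(0.5, 0.5))
  expect_equal(normalize_attention(c(log(2), 0)), c(2 / 3, 1 / 3))
  expect_error(normalize_attention(numeric(0)), class = "input_error")
})

test_that("neighbor aggregation is the stated convex combination", {
  f <- rbind(c(1, 0, 0), c(0, 1, 0))
  expect_equal(aggregate_neighbors(1, f[1, , drop = FALSE]), c(1, 0, 0))
  expect_equal(aggregate_neighbors(c(0.25, 0.75), f), c(0.25, 0.75, 0))
  v <- c(2, 3, 4)
  expect_equal(aggregate_neighbors(rep(1 / 3, 3), rbind(v, v, v)), v)
  expect_error(aggregate_neighbors(c(0.5, 0.5), f[1, , drop = FALSE]),
               class = "shape_error")
})

test_that("multiple-operator combiner matches the scalar-loop oracle", {
  set.seed(21)
  for (trial in 1:20) {
    d <- sample(2:6, 1); k <- sample(1:4, 1)
    p <- ldapred:::init_head_params(d, k)
    h_i <- rnorm(d); h_Ni <- rnorm(d)
    got <- multi_operator_aggregate(h_i, h_Ni, p)
    want <- oracle_multi_operator(h_i, h_Ni, p$W1_sum, p$W1_cat, 0.2)
    expect_equal(got, want, tolerance = 1e-12)
  }
  # zero inputs -> zero output; zero concat branch -> sum branch alone
  p <- ldapred:::init_head_params(3, 2)
  expect_equal(multi_operator_aggregate(rep(0, 3), rep(0, 3), p), c(0, 0))
  p0 <- p; p0$W1_cat[] <- 0
  b_sum <- ldapred:::leaky_relu(drop(crossprod(p0$W1_sum, c(1, 2, 3) + c(0, 1, 0))), 0.2)
  expect_equal(multi_operator_aggregate(c(1, 2, 3), c(0, 1, 0), p0), b_sum)
})

test_that("encoder output has heads x neurons columns, split diseases-first", {
  d <- small_dataset(seed = 5)
  cfg <- small_config()
  stack <- build_similarity_stack(d$assoc, d$ontology, cfg)
  params <- init_model_params(ncol(d$assoc), nrow(d$assoc), cfg)
  emb <- encode_nodes(stack$X, stack$neighbor_index, params, cfg)
  expect_equal(ncol(emb$M), cfg$n_heads * cfg$neurons)
  expect_equal(nrow(emb$Md), ncol(d$assoc))
  expect_equal(nrow(emb$Ml), nrow(d$assoc))
  expect_identical(emb$M, rbind(emb$Md, emb$Ml))
  expect_true(all(is.finite(emb$M)))
})

test_that("attention coefficients sum to one over every neighborhood", {
  d <- small_dataset(seed = 9)
  cfg <- small_config()
  stack <- build_similarity_stack(d$assoc, d$ontology, cfg)
  params <- init_model_params(ncol(d$assoc), nrow(d$assoc), cfg)
  fw <- ldapred:::gat_forward(unclass(stack$X), stack$neighbor_index$adjacency,
                              params, cfg$leaky_slope, cfg$variant)
  for (cache in fw$caches) {
    expect_true(max(abs(rowSums(cache$alpha) - 1)) < 1e-9)
    expect_true(all(cache$alpha >= 0))
    # aggregated features stay inside the neighbor convex hull
    adj <- stack$neighbor_index$adjacency
    X <- unclass(stack$X)
    for (i in sample(nrow(X), 4)) {
      nb <- which(adj[i, ])
      expect_true(all(cache$HN[i, ] <=
                        apply(X[nb, , drop = FALSE], 2, max) + 1e-12))
      expect_true(all(cache$HN[i, ] >=
                        apply(X[nb, , drop = FALSE], 2, min) - 1e-12))
    }
  }
})

test_that("analytic gradients match finite differences on a small instance", {
  d <- small_dataset(seed = 2, nl = 6, nd = 5)
  cfg <- default_config(n_heads = 2, neurons = 3, rank = 3, seed = 4,
                        engine = "r")
  stack <- build_similarity_stack(d$assoc, d$ontology, cfg)
  A <- unclass(d$assoc); X <- unclass(stack$X)
  msk <- stack$neighbor_index$adjacency
  params <- init_model_params(5, 6, cfg, seed = 4)
  fb <- ldapred:::forward_backward(A, X, msk, params, cfg)
  lossfn <- function(p) ldapred:::forward_backward(A, X, msk, p, cfg)$loss
  set.seed(1)
  check_tensor <- function(get, set, grad) {
    ii <- sample(length(grad), min(5, length(grad)))
    for (i in ii) {
      p1 <- set(params, i, get(params)[i] + 1e-6)
      p2 <- set(params, i, get(params)[i] - 1e-6)
      num <- (lossfn(p1) - lossfn(p2)) / 2e-6
      expect_equal(unname(grad[i]), num, tolerance = 1e-4)
    }
  }
  for (h in 1:2) for (nm in c("W", "a", "W1_sum", "W1_cat")) {
    check_tensor(function(p) p$heads[[h]][[nm]],
                 function(p, i, v) { p$heads[[h]][[nm]][i] <- v; p },
                 fb$grads$heads[[h]][[nm]])
  }
  for (nm in c("Pd", "Pl")) {
    check_tensor(function(p) p[[nm]],
                 function(p, i, v) { p[[nm]][i] <- v; p },
                 fb$grads[[nm]])
  }
})

test_that("encoding is permutation-equivariant over node order", {
  # permuting disease order (and all aligned inputs) permutes the
  # disease embedding block identically
  d <- small_dataset(seed = 3)
  cfg <- small_config()
  stack <- build_similarity_stack(d$assoc, d$ontology, cfg)
  params <- init_model_params(ncol(d$assoc), nrow(d$assoc), cfg)
  emb <- encode_nodes(stack$X, stack$neighbor_index, params, cfg)

  perm_d <- sample(ncol(d$assoc))
  a2 <- association_matrix(unclass(d$assoc)[, perm_d])
  stack2 <- build_similarity_stack(a2, d$ontology, cfg)
  # permute the per-feature parameters consistently: feature axis is
  # (lncRNAs, diseases), so disease coordinates shift within it
  nl <- nrow(d$assoc)
  fperm <- c(seq_len(nl), nl + perm_d)
  params2 <- params
  for (h in seq_along(params2$heads)) {
    params2$heads[[h]]$W <- params$heads[[h]]$W[fperm]
    dtot <- length(fperm)
    params2$heads[[h]]$a <- params$heads[[h]]$a[c(fperm, dtot + fperm)]
    params2$heads[[h]]$W1_sum <- params$heads[[h]]$W1_sum[fperm, , drop = FALSE]
    params2$heads[[h]]$W1_cat <-
      params$heads[[h]]$W1_cat[c(fperm, dtot + fperm), , drop = FALSE]
  }
  emb2 <- encode_nodes(stack2$X, stack2$neighbor_index, params2, cfg)
  expect_equal(unname(emb2$Md), unname(emb$Md[perm_d, , drop = FALSE]),
               tolerance = 1e-10)
  expect_equal(unname(emb2$Ml), unname(emb$Ml), tolerance = 1e-10)
})
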