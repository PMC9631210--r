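test_that("reconstruction matches a hand-computed outer product + sigmoid", {
  emb <- structure(list(M = rbind(c(1, 2), c(0, 1), c(2, 0)),
                        Md = rbind(d1 = c(1, 2)),
                        Ml = rbind(l1 = c(0, 1), l2 = c(2, 0))),
                   class = "node_embeddings")
  params <- list(Pd = diag(2), Pl = diag(2))
  sc <- reconstruct_associations(emb, params)
  want <- 1 / (1 + exp(-rbind(c(2), c(2))))
  expect_equal(unname(sc), unname(want))
  raw <- reconstruct_associations(emb, params, raw = TRUE)
  expect_equal(unname(raw), rbind(2, 2))
  # zero projections -> all scores 0.5
  p0 <- list(Pd = matrix(0, 2, 2), Pl = matrix(0, 2, 2))
  expect_true(all(reconstruct_associations(emb, p0) == 0.5))
  # rank-1 projections give a rank-1 raw score matrix
  p1 <- list(Pd = cbind(c(1, 1)), Pl = cbind(c(1, 0)))
  expect_equal(qr(reconstruct_associations(emb, p1, raw = TRUE))$rank, 1L)
  emb$M[1] <- NaN
  expect_error(reconstruct_associations(emb, params), class = "input_error")
})

test_that("loss equals a per-entry loop oracle and is zero at perfection", {
  set.seed(8)
  a <- association_matrix(matrix(rbinom(9, 1, 0.5), 3,
                                 dimnames = list(paste0("l", 1:3),
                                                 paste0("d", 1:3))))
  recon <- matrix(runif(9), 3)
  want <- 0
  for (i in 1:3) for (j in 1:3) want <- want + (unclass(a)[i, j] - recon[i, j])^2
  expect_equal(association_loss(a, recon, lambda = 1), want,
               tolerance = 1e-12)
  expect_equal(association_loss(a, unclass(a), params = NULL), 0)
  expect_error(association_loss(a, matrix(0, 2, 2)), class = "shape_error")
})

test_that("training is reproducible and decreases the loss", {
  d <- small_dataset(seed = 6)
  cfg <- small_config(epochs = 30)
  f1 <- train_model(d$assoc, d$ontology, cfg)
  f2 <- train_model(d$assoc, d$ontology, cfg)
  expect_identical(f1$losses, f2$losses)
  expect_identical(f1$scores, f2$scores)
  expect_lt(f1$losses[length(f1$losses)], f1$losses[1])
  expect_true(all(f1$scores >= 0 & f1$scores <= 1))
  expect_error(train_model(d$assoc, d$ontology, small_config(epochs = 0)))
})

test_that("compiled and reference training engines agree", {
  d <- small_dataset(seed = 12)
  cfg <- small_config(epochs = 8)
  fc <- train_model(d$assoc, d$ontology, cfg)
  cfg$engine <- "r"
  fr <- train_model(d$assoc, d$ontology, cfg)
  expect_equal(fc$losses, fr$losses, tolerance = 1e-10)
  expect_equal(fc$scores, fr$scores, tolerance = 1e-10)
  for (v in c("plain_gat")) {
    c2 <- small_config(epochs = 8, variant = v)
    a <- train_model(d$assoc, d$ontology, c2)
    c2$engine <- "r"
    b <- train_model(d$assoc, d$ontology, c2)
    expect_equal(a$losses, b$losses, tolerance = 1e-10)
  }
})

test_that("median loss trajectory is non-increasing after burn-in", {
  traj <- sapply(0:9, function(s) {
    d <- small_dataset(seed = s)
    train_model(d$assoc, config = small_config(epochs = 60, seed = s))$losses
  })
  med <- apply(traj, 1, stats::median)
  # downward trend after burn-in: any residual Adam oscillation stays
  # below 0.5% of the running loss and the tail sits below the burn-in
  ups <- diff(med[10:60])
  expect_true(all(ups <= 0.005 * med[10:59]))
  expect_lt(med[60], med[10])
  expect_true(all(diff(med[25:60]) <= 1e-8))
})

test_that("planted low-rank structure is recovered above 0.85 held-out AUC", {
  aucs <- sapply(0:9, function(s) {
    spec <- synthetic_spec(nl = 20, nd = 30, n_blocks = 2,
                           density_in = 0.95, density_out = 0.02, seed = s)
    syn <- generate_association_matrix(spec)
    ont <- generate_dag_forest(spec)
    m <- mask_entries(syn$assoc, fraction = 0.3, seed = s + 100)
    fit <- train_model(m$train, ont, default_config(seed = s))
    neg <- which(unclass(syn$assoc) == 0)
    sc <- fit$scores
    lab <- rep(c(1, 0), c(nrow(m$heldout), length(neg)))
    roc_auc(c(sc[m$heldout], sc[neg]), lab)
  })
  expect_gt(mean(aucs), 0.85)
})

test_that("trained model outperforms frozen random projections", {
  aucs <- sapply(0:4, function(s) {
    spec <- synthetic_spec(nl = 20, nd = 30, n_blocks = 2,
                           density_in = 0.95, density_out = 0.02, seed = s)
    syn <- generate_association_matrix(spec)
    ont <- generate_dag_forest(spec)
    m <- mask_entries(syn$assoc, fraction = 0.3, seed = s + 100)
    neg <- which(unclass(syn$assoc) == 0)
    lab <- rep(c(1, 0), c(nrow(m$heldout), length(neg)))
    one <- function(cfg) {
      sc <- train_model(m$train, ont, cfg)$scores
      roc_auc(c(sc[m$heldout], sc[neg]), lab)
    }
    c(trained = one(default_config(seed = s)),
      frozen = one(default_config(seed = s, train = FALSE)))
  })
  expect_gt(mean(aucs["trained", ]), mean(aucs["frozen", ]))
})

test_that("cold-start columns receive finite, informative scores", {
  d <- small_dataset(seed = 4, nl = 20, nd = 15)
  j <- colnames(d$assoc)[which(colSums(d$assoc) >= 2)[1]]
  m <- mask_entries(d$assoc, columns = j, seed = 1)
  expect_true(all(unclass(m$train)[, j] == 0))
  fit <- train_model(m$train, d$ontology, small_config(epochs = 60))
  col <- fit$scores[, j]
  expect_true(all(is.finite(col)))
  expect_gt(stats::var(col), 0)
})

test_that("candidate ranking orders by score with lexicographic ties", {
  sc <- matrix(c(0.9, 0.2, 0.9, 0.5), 4, 1,
               dimnames = list(c("lb", "lc", "la", "ld"), "dz"))
  a <- association_matrix(matrix(c(0, 0, 0, 1), 4, 1,
                                 dimnames = list(rownames(sc), "dz")))
  r <- rank_candidates(sc, "dz", assoc = a, exclude_known = TRUE)
  expect_equal(r$lncrna_id, c("la", "lb", "lc"))  # ld excluded (known)
  expect_equal(nrow(r), 3)
  all_eq <- matrix(0.5, 4, 1, dimnames = dimnames(sc))
  r2 <- rank_candidates(all_eq, "dz", exclude_known = FALSE)
  expect_equal(r2$lncrna_id, sort(rownames(sc)))
  expect_equal(nrow(rank_candidates(sc, "dz", assoc = a, top = 2,
                                    exclude_known = TRUE)), 2)
  expect_error(rank_candidates(sc, "nope", assoc = a),
               class = "lookup_error")
})

test_that("the plain matrix-completion variant trains and scores", {
  d <- small_dataset(seed = 7)
  fit <- train_model(d$assoc, config = small_config(variant = "plain_mc",
                                                    epochs = 50))
  expect_equal(dim(fit$scores), dim(d$assoc))
  expect_lt(fit$losses[50], fit$losses[1])
  expect_null(fit$embeddings)
})
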