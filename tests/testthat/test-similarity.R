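test_that("functional similarity follows best-match averaging", {
  a <- association_matrix(rbind(l1 = c(1, 0, 0), l2 = c(1, 0, 0),
                                l3 = c(0, 1, 0), l4 = c(0, 0, 0)),
                          disease_ids = c("d1", "d2", "d3"))
  s <- 0.4
  ds <- similarity_matrix(matrix(c(1, s, 0, s, 1, 0, 0, 0, 1), 3,
                                 dimnames = list(c("d1", "d2", "d3"),
                                                 c("d1", "d2", "d3"))),
                          kind = "semantic")
  fs <- lncrna_functional_similarity(a, ds)
  expect_equal(fs["l1", "l2"], 1)        # identical single-disease sets
  expect_equal(fs["l1", "l3"], s)        # (s + s) / 2
  expect_equal(unname(fs["l4", ]), rep(0, 4))  # no associations -> zero row
  expect_identical(attr(fs, "no_association"), "l4")
  expect_equal(fs["l1", "l1"], 1)
  expect_true(max(abs(fs - t(fs))) == 0)
})

test_that("gaussian kernel: closed form, bounds, permutation equivariance", {
  p <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE,
              dimnames = list(c("d1", "d2"), NULL))
  g <- gaussian_profile_kernel(p)
  expect_equal(g["d1", "d2"], exp(-2), tolerance = 1e-15)
  expect_equal(unname(diag(g)), c(1, 1))

  set.seed(11)
  q <- matrix(rbinom(60, 1, 0.4), 6,
              dimnames = list(paste0("n", 1:6), NULL))
  q[1, ] <- 1  # ensure a nonzero profile
  k <- gaussian_profile_kernel(q)
  expect_true(all(k > 0 & k <= 1))
  expect_equal(unname(diag(k)), rep(1, 6))
  perm <- sample(6)
  kp <- gaussian_profile_kernel(q[perm, , drop = FALSE])
  expect_equal(bare(kp), bare(k[perm, perm]))
  expect_equal(attr(kp, "bandwidth"), attr(k, "bandwidth"))

  expect_error(gaussian_profile_kernel(matrix(0, 3, 4)),
               class = "input_error")
})

test_that("disease integration adds where semantic is nonzero, else Gaussian", {
  ids <- c("a", "b")
  ds <- similarity_matrix(matrix(c(1, 0.3, 0.3, 1), 2,
                                 dimnames = list(ids, ids)), "semantic")
  ds0 <- similarity_matrix(matrix(0, 2, 2, dimnames = list(ids, ids)),
                           "semantic")
  gd <- similarity_matrix(matrix(c(1, 0.4, 0.4, 1), 2,
                                 dimnames = list(ids, ids)), "gaussian")
  fused <- integrate_disease_similarity(ds, gd)
  expect_equal(fused["a", "b"], 0.7)           # 0.3 + 0.4
  expect_equal(bare(integrate_disease_similarity(ds0, gd)), bare(gd))
  expect_equal(integrate_disease_similarity(ds, gd, average = TRUE)["a", "b"],
               0.35)
  bad <- similarity_matrix(matrix(0.4, 3, 3,
                                  dimnames = list(letters[1:3], letters[1:3])),
                           "gaussian")
  expect_error(integrate_disease_similarity(ds, bad),
               class = "alignment_error")
})

test_that("lncRNA integration is pass-through, and idempotent on its output", {
  ids <- c("x", "y")
  fs <- similarity_matrix(matrix(c(1, 0.6, 0.6, 1), 2,
                                 dimnames = list(ids, ids)), "functional")
  fs0 <- similarity_matrix(matrix(0, 2, 2, dimnames = list(ids, ids)),
                           "functional")
  gl <- similarity_matrix(matrix(c(1, 0.2, 0.2, 1), 2,
                                 dimnames = list(ids, ids)), "gaussian")
  fused <- integrate_lncrna_similarity(fs, gl)
  expect_equal(fused["x", "y"], 0.6)
  expect_equal(integrate_lncrna_similarity(fs0, gl)["x", "y"], 0.2)
  # applying the rule again with the fused output changes nothing
  again <- integrate_lncrna_similarity(
    similarity_matrix(unclass(fused), "functional"), gl)
  expect_equal(unname(again), unname(fused))
})

test_that("feature matrix is block-anti-diagonal with bit-exact blocks", {
  nd <- 2; nl <- 3
  ds_i <- similarity_matrix(matrix(c(1.2, 0.4, 0.4, 1.5), 2,
                                   dimnames = list(c("d1", "d2"),
                                                   c("d1", "d2"))),
                            "integrated")
  set.seed(4)
  fsv <- matrix(runif(9), 3); fsv <- (fsv + t(fsv)) / 2
  dimnames(fsv) <- list(paste0("l", 1:3), paste0("l", 1:3))
  fs_i <- similarity_matrix(fsv, "integrated")
  X <- assemble_feature_matrix(ds_i, fs_i)
  expect_equal(dim(X), c(5L, 5L))
  expect_equal(unname(X[1:2, 1:3]), matrix(0, 2, 3))    # zero block
  expect_equal(unname(X[3:5, 4:5]), matrix(0, 3, 2))    # zero block
  expect_identical(unname(X[1:2, 4:5]), bare(ds_i))
  expect_identical(unname(X[3:5, 1:3]), bare(fs_i))
  expect_identical(attr(X, "nd"), 2L)
  expect_identical(attr(X, "nl"), 3L)
})

test_that("similarity matrices reject asymmetry and wrong shapes", {
  m <- matrix(c(1, 0.5, 0.1, 1), 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(similarity_matrix(m, "semantic"), class = "input_error")
  expect_error(similarity_matrix(matrix(0, 2, 3), "semantic"),
               class = "input_error")
})
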