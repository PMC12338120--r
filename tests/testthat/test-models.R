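make_toy_model <- function(kind = "gpcn", seed = 5, maxit = 25) {
  h <- build_hierarchy(list(build_tube_graph(tube_spec(4, 3, 0)),
                            build_tube_graph(tube_spec(2, 3, 0)),
                            build_tube_graph(tube_spec(1, 3, 0))),
                       maxit = maxit)
  gcn_model(kind, list(member_spec(c(4, 4), c(6, 1)),
                       member_spec(c(4, 4), c(6, 1)),
                       member_spec(c(5, 5), c(6, 1))),
            hierarchy = h, input_dim = 3, seed = seed)
}

test_that("gcn_forward applies the layerwise update rule", {
  Z <- as.matrix(laplacian(build_tube_graph(tube_spec(2, 3, 0))))
  X <- matrix(seq_len(12) / 10, 6, 2)
  # all-zero parameters with ReLU: zero output
  zero <- list(list(W = matrix(0, 2, 3), b = numeric(3), activation = "relu"))
  expect_equal(gcn_forward(Z, X, zero), matrix(0, 6, 3), ignore_attr = TRUE)
  # zero structure matrix with linear activation: bias broadcast
  lin <- list(list(W = matrix(1, 2, 2), b = c(3, -1), activation = "linear"))
  out <- gcn_forward(matrix(0, 6, 6), X, lin)
  expect_equal(out, matrix(rep(c(3, -1), each = 6), 6, 2), ignore_attr = TRUE)
  # random instance against the loop-written oracle
  set.seed(71)
  params <- init_member_params(member_spec(c(3, 2), c(4, 1)), 2)
  X5 <- matrix(rnorm(10), 5, 2)
  Z5 <- random_laplacian(5)
  mine <- member_forward(Z5, X5, params)
  expect_equal(mine, oracle_member_forward(Z5, X5, params), tolerance = 1e-10)
  expect_error(gcn_forward(Z5, X5, list(list(W = matrix(0, 3, 1),
                                             b = 0, activation = "relu"))),
               "mismatch")
})

test_that("member dense head consumes the concatenated GCN outputs", {
  spec <- member_spec(c(3, 5, 2), c(7, 1))
  params <- init_member_params(spec, 4)
  expect_equal(nrow(params$dense[[1]]$W), sum(spec$gcn_filters))
  # zero dense weights: output equals the final bias
  params$dense[[2]]$W[] <- 0
  params$dense[[2]]$b <- 0.37
  Z <- random_laplacian(6)
  out <- member_forward(Z, matrix(rnorm(24), 6, 4), params)
  expect_equal(as.numeric(out), rep(0.37, 6))
})

test_that("GPCN forward is the fine member plus prolonged coarse members", {
  set.seed(81)
  m <- make_toy_model("gpcn")
  X <- matrix(rnorm(12 * 3), 12, 3)
  # sum-of-parts oracle
  P12 <- m$pairwise_P[[1]]; P13 <- P12 %*% m$pairwise_P[[2]]
  expected <- member_forward(m$Z[[1]], X, m$members[[1]]) +
    P12 %*% member_forward(m$Z[[2]], crossprod(P12, X), m$members[[2]]) +
    P13 %*% member_forward(m$Z[[3]], crossprod(P13, X), m$members[[3]])
  expect_equal(model_forward(m, X), as.matrix(expected), tolerance = 1e-10)
  # zeroing the coarse members leaves the fine member alone
  m0 <- m
  for (i in 2:3) {
    for (l in seq_along(m0$members[[i]]$dense)) {
      m0$members[[i]]$dense[[l]]$W[] <- 0
      m0$members[[i]]$dense[[l]]$b[] <- 0
    }
  }
  expect_equal(model_forward(m0, X),
               as.matrix(member_forward(m0$Z[[1]], X, m0$members[[1]])),
               tolerance = 1e-12)
})

test_that("ensemble output is linear in each member's output layer", {
  set.seed(91)
  m <- make_toy_model("gpcn")
  X <- matrix(rnorm(36), 12, 3)
  base <- model_forward(m, X)
  m1 <- m
  m1$members[[1]]$dense[[2]]$W <- 2 * m1$members[[1]]$dense[[2]]$W
  m1$members[[1]]$dense[[2]]$b <- 2 * m1$members[[1]]$dense[[2]]$b
  doubled <- model_forward(m1, X)
  fine <- member_forward(m$Z[[1]], X, m$members[[1]])
  expect_equal(doubled - base, as.matrix(fine), tolerance = 1e-10)
})

test_that("a 1-level model reduces to its member", {
  set.seed(101)
  g <- build_tube_graph(tube_spec(4, 3, 0))
  h <- build_hierarchy(list(g))
  m <- gcn_model("gpcn", list(member_spec(c(4, 4), c(6, 1))), hierarchy = h,
                 input_dim = 3, seed = 101)
  X <- matrix(rnorm(36), 12, 3)
  expect_equal(model_forward(m, X),
               as.matrix(member_forward(m$Z[[1]], X, m$members[[1]])))
})

test_that("N-GCN members aggregate with cached structure-matrix powers", {
  set.seed(111)
  g <- build_tube_graph(tube_spec(4, 3, 0))
  Z <- laplacian(g)
  m <- gcn_model("ngcn", list(member_spec(c(3, 3), c(5, 1)),
                              member_spec(c(3, 3), c(5, 1))),
                 graph = g, radii = c(1, 2), input_dim = 3, seed = 111)
  X <- matrix(rnorm(36), 12, 3)
  Z2 <- as.matrix(Z %*% Z)
  expect_lt(max(abs(as.matrix(m$Z[[2]]) - Z2)), 1e-12)
  expected <- member_forward(Z, X, m$members[[1]]) +
    member_forward(Z2, X, m$members[[2]])
  expect_equal(model_forward(m, X), as.matrix(expected), tolerance = 1e-10)
  expect_equal(ngcn_forward(Z, X, c(1, 2), m$members),
               as.matrix(expected), tolerance = 1e-10)
  # radius 1 alone is the plain single GCN
  expect_equal(ngcn_forward(Z, X, 1, m$members[1]),
               as.matrix(member_forward(Z, X, m$members[[1]])))
})

test_that("diffpool assignments live on the simplex and pool by block sums", {
  set.seed(121)
  Z <- random_laplacian(8)
  X <- matrix(rnorm(16), 8, 2)
  aux <- list(W = matrix(rnorm(6), 2, 3), b = rnorm(3))
  dp <- diffpool_coarsen(Z, X, aux)
  expect_equal(rowSums(dp$S), rep(1, 8))
  expect_true(all(dp$S >= 0))
  expect_equal(dim(dp$Z_coarse), c(3L, 3L))
  expect_equal(dim(dp$X_coarse), c(3L, 2L))
  expect_equal(dp$Z_coarse, crossprod(dp$S, Z %*% dp$S), tolerance = 1e-12)
  # hard 0/1 partition: pooled Z equals the block-sum oracle
  part <- rep(1:2, each = 4)
  aux_hard <- list(W = matrix(0, 2, 2), b = c(0, 0))
  logits <- matrix(-1e4, 8, 2); logits[cbind(1:8, part)] <- 1e4
  S <- exp(logits - apply(logits, 1, max)); S <- S / rowSums(S)
  blocksum <- matrix(0, 2, 2)
  for (i in 1:8) for (j in 1:8)
    blocksum[part[i], part[j]] <- blocksum[part[i], part[j]] + Z[i, j]
  expect_equal(crossprod(S, Z %*% S), blocksum, tolerance = 1e-9)
  expect_error(diffpool_coarsen(Z, X, list(W = matrix(0, 2, 9),
                                           b = numeric(9))), "smaller")
})

test_that("training-tape forward agrees with the numeric forward", {
  set.seed(131)
  for (kind in c("gpcn", "agpcn", "diffpool")) {
    m <- make_toy_model(kind, seed = 131)
    X1 <- matrix(rnorm(36), 12, 3); X2 <- matrix(rnorm(36), 12, 3)
    Zb <- lapply(m$Z, function(Z)
      methods::as(Matrix::bdiag(rep(list(Z), 2)), "CsparseMatrix"))
    tl <- gpcn:::build_loss_tape(m, rbind(X1, X2), matrix(0, 24, 1), 2, Zb)
    pred <- gpcn:::tp_value(tl$tp, tl$pred)
    expect_equal(pred[1:12, , drop = FALSE], model_forward(m, X1),
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(pred[13:24, , drop = FALSE], model_forward(m, X2),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("adaptive prolongations move under one optimizer step", {
  set.seed(141)
  m <- make_toy_model("agpcn", seed = 141)
  x <- array(rnorm(4 * 12 * 3), c(4, 12, 3))
  y <- matrix(rnorm(4 * 12), 4, 12)
  P_before <- m$pairwise_P[[1]]
  out <- train_model(m, x, y, x, y,
                     config = train_config(epochs = 1, batch_size = 2,
                                           batches_per_epoch = 2, seed = 1),
                     schedule = schedule_spec("joint"))
  expect_gt(max(abs(out$model$pairwise_P[[1]] - P_before)), 1e-9)
  # static GPCN leaves P untouched
  m2 <- make_toy_model("gpcn", seed = 141)
  out2 <- train_model(m2, x, y, x, y,
                      config = train_config(epochs = 1, batch_size = 2,
                                            batches_per_epoch = 2, seed = 1),
                      schedule = schedule_spec("joint"))
  expect_identical(out2$model$pairwise_P[[1]], m2$pairwise_P[[1]])
})

test_that("model presets expose the reference architecture configurations", {
  p <- model_preset("3-level GPCN", scale = "paper")
  expect_equal(p$kind, "gpcn")
  expect_equal(p$members[[1]]$gcn_filters, rep(16L, 3))  # fine level
  expect_equal(p$members[[3]]$gcn_filters, rep(64L, 3))  # coarse level
  expect_equal(p$members[[1]]$dense_filters, c(256L, 32L, 8L, 1L))
  n <- model_preset("N-GCN (1,2,4,8,16)")
  expect_equal(n$radii, c(1, 2, 4, 8, 16))
  expect_length(n$members, 5)
  expect_error(model_preset("nope"), "unknown preset")
})
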