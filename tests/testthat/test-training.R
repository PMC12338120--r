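test_that("normalization: training stats give zero mean, unit sd, round trip", {
  set.seed(151)
  x <- array(rnorm(20 * 6 * 3, mean = 2, sd = 3), c(20, 6, 3))
  y <- matrix(rnorm(20 * 6, mean = -1, sd = 0.5), 20, 6)
  st <- normalize_stats(x, y)
  nx <- apply_normalization(x, y, st)
  expect_lt(max(abs(apply(nx$x, c(2, 3), mean))), 1e-12)
  expect_lt(max(abs(apply(nx$x, c(2, 3), stats::sd) - 1)), 1e-12)
  expect_lt(max(abs(colMeans(nx$y))), 1e-12)
  # round trip
  back <- apply_normalization(nx$x, nx$y, st, invert = TRUE)
  expect_equal(back$x, x, tolerance = 1e-12)
  expect_equal(back$y, y, tolerance = 1e-12)
  # held-out frame reproduces a hand-computed z-score
  xh <- array(rnorm(1 * 6 * 3), c(1, 6, 3))
  nh <- apply_normalization(x = xh, stats = st)$x
  expect_equal(nh[1, 4, 2], (xh[1, 4, 2] - st$x_mean[4, 2]) / st$x_sd[4, 2])
  # constant feature floors the sd with a warning
  x[, 2, 1] <- 7
  expect_warning(st2 <- normalize_stats(x, y), "floored")
  expect_gte(min(st2$x_sd), 1e-8)
})

test_that("nmse: zero at equality, about 1 for a null predictor, loop oracle", {
  set.seed(161)
  y <- matrix(rnorm(3 * 5), 3, 5)
  expect_equal(nmse(y, y), 0)
  # all-zero prediction in normalized space on standardized targets
  ybig <- matrix(rnorm(4000 * 2), 4000, 2)
  yn <- scale(ybig)
  expect_equal(nmse(matrix(0, 4000, 2), yn), 1, tolerance = 0.01)
  # explicit loop-computed mean on a 3-frame toy
  p <- matrix(rnorm(15), 3, 5)
  acc <- 0
  for (i in 1:3) for (j in 1:5) acc <- acc + (p[i, j] - y[i, j])^2
  expect_equal(nmse(p, y), acc / 15, tolerance = 1e-12)
})

test_that("FLOP formulas are the declared cost-model products", {
  expect_equal(flops_gcn_layer(1, 1, 1, 1), 2)
  g <- build_tube_graph(tube_spec(48, 13, 3))
  z <- nnz(laplacian(g))
  expect_equal(flops_gcn_layer(624, 10, z, 64), 624 * 10 * (z + 64))
  # linear scaling in the feature width
  expect_equal(flops_gcn_layer(10, 6, 40, 8), 3 * flops_gcn_layer(10, 2, 40, 8))
  expect_equal(flops_dense(1, 2, 3), 6)
  expect_equal(flops_matmul(624, 10, 72), 624 * 10 * 72)
})

test_that("event ledger adds up over members and levels", {
  h <- build_hierarchy(list(build_tube_graph(tube_spec(4, 3, 0)),
                            build_tube_graph(tube_spec(2, 3, 0))), maxit = 25)
  m <- gcn_model("gpcn", list(member_spec(c(3, 3), c(4, 1)),
                              member_spec(c(3, 3), c(4, 1))),
                 hierarchy = h, input_dim = 3, seed = 1)
  cfg <- train_config(batch_size = 2, batches_per_epoch = 5, seed = 1)
  ev_joint <- flops_event(m, 1:2, cfg)
  ev1 <- flops_event(m, 1, cfg)
  ev2 <- flops_event(m, 2, cfg)
  # per-frame totals are the breakdown sums
  expect_equal(ev_joint$per_frame,
               sum(ev_joint$breakdown$forward + ev_joint$breakdown$projection +
                   ev_joint$breakdown$backward))
  expect_equal(ev_joint$total, ev_joint$per_frame * 10)
  # a joint epoch covers the same computation as the per-level backward
  # events plus one shared forward sweep
  fwd <- sum(ev_joint$breakdown$forward + ev_joint$breakdown$projection)
  expect_equal(ev_joint$per_frame,
               (ev1$per_frame - fwd) + (ev2$per_frame - fwd) + fwd)
  # member forward cost oracle: layer-by-layer formula sum
  spec <- member_spec(c(3, 3), c(4, 1))
  zf <- nnz(m$Z[[1]])
  byhand <- flops_gcn_layer(12, 3, zf, 3) + flops_gcn_layer(12, 3, zf, 3) +
    flops_dense(12, 6, 4) + flops_dense(12, 4, 1)
  expect_equal(ev_joint$breakdown$forward[1], byhand)
})

test_that("schedule sequences unroll the multigrid recursion", {
  lv <- function(l) as.integer(l)
  # 3 levels, gamma = 1: the V cycle
  expect_equal(schedule_sequence(3, schedule_spec("mu_cycle", gamma = 1)),
               lapply(c(1, 2, 3, 2, 1), lv))
  # gamma = 0 degenerates to fine-only
  expect_equal(schedule_sequence(3, schedule_spec("mu_cycle", gamma = 0)),
               list(1L))
  # gamma = 2, by-hand unroll
  expect_equal(schedule_sequence(3, schedule_spec("mu_cycle", gamma = 2)),
               lapply(c(1, 2, 3, 3, 2, 2, 3, 3, 2, 1), lv))
  # one level: any gamma trains the only member
  expect_equal(schedule_sequence(1, schedule_spec("mu_cycle", gamma = 3)),
               list(1L))
  expect_equal(schedule_sequence(3, schedule_spec("joint")), list(1:3))
  c2f <- schedule_sequence(3, schedule_spec("coarse_to_fine"))
  expect_equal(c2f[[1]], 3L)
  expect_equal(sort(c2f[[2]]), 2:3)
  expect_equal(sort(c2f[[3]]), 1:3)
  expect_true(attr(c2f, "gated"))
  expect_error(schedule_spec("mu_cycle", gamma = 4), "gamma")
  expect_error(schedule_spec("joint", gamma = 1), "only meaningful")
})

test_that("zero learning rate leaves parameters and loss unchanged", {
  set.seed(171)
  h <- build_hierarchy(list(build_tube_graph(tube_spec(4, 3, 0)),
                            build_tube_graph(tube_spec(2, 3, 0))), maxit = 25)
  m <- gcn_model("agpcn", list(member_spec(c(3, 3), c(4, 1)),
                               member_spec(c(3, 3), c(4, 1))),
                 hierarchy = h, input_dim = 3, seed = 171)
  x <- array(rnorm(6 * 12 * 3), c(6, 12, 3))
  y <- matrix(rnorm(6 * 12), 6, 12)
  before <- gpcn:::flatten_params(m)
  out <- train_model(m, x, y, x, y,
                     config = train_config(epochs = 2, batch_size = 2,
                                           batches_per_epoch = 2, lr = 0,
                                           seed = 3))
  expect_equal(gpcn:::flatten_params(out$model), before, tolerance = 0)
  expect_equal(out$history$val_nmse[1], out$history$val_nmse[2])
})

test_that("fixed seeds reproduce identical training histories", {
  set.seed(181)
  g <- build_tube_graph(tube_spec(4, 3, 0))
  h <- build_hierarchy(list(g))
  x <- array(rnorm(10 * 12 * 3), c(10, 12, 3))
  y <- matrix(rnorm(10 * 12), 10, 12)
  run <- function() {
    m <- gcn_model("gpcn", list(member_spec(c(3, 3), c(4, 1))),
                   hierarchy = h, input_dim = 3, seed = 9)
    train_model(m, x, y, x, y,
                config = train_config(epochs = 3, batch_size = 2,
                                      batches_per_epoch = 3, seed = 9))$history
  }
  expect_identical(run(), run())
})

test_that("running-minimum validation error is monotone non-increasing", {
  set.seed(191)
  g <- build_tube_graph(tube_spec(4, 3, 0))
  h <- build_hierarchy(list(g))
  m <- gcn_model("gpcn", list(member_spec(c(4, 4), c(6, 1))),
                 hierarchy = h, input_dim = 3, seed = 19)
  x <- array(rnorm(10 * 12 * 3), c(10, 12, 3))
  y <- matrix(rnorm(10 * 12), 10, 12)
  out <- train_model(m, x, y, x, y,
                     config = train_config(epochs = 6, batch_size = 2,
                                           batches_per_epoch = 3, seed = 19))
  expect_true(all(diff(out$history$min_val_nmse) <= 0))
  expect_true(all(diff(out$history$cum_flops) > 0))
})

test_that("mu-cycle and coarse-to-fine schedules drive per-level updates", {
  set.seed(201)
  h <- build_hierarchy(list(build_tube_graph(tube_spec(4, 3, 0)),
                            build_tube_graph(tube_spec(2, 3, 0))), maxit = 25)
  x <- array(rnorm(8 * 12 * 3), c(8, 12, 3))
  y <- matrix(rnorm(8 * 12), 8, 12)
  m <- gcn_model("gpcn", list(member_spec(c(3, 3), c(4, 1)),
                              member_spec(c(3, 3), c(4, 1))),
                 hierarchy = h, input_dim = 3, seed = 20)
  out <- train_model(m, x, y, x, y,
                     config = train_config(epochs = 6, batch_size = 2,
                                           batches_per_epoch = 2, seed = 20),
                     schedule = schedule_spec("mu_cycle", gamma = 1))
  # V-cycle on two levels: 1, 2, 1 repeating
  expect_equal(out$history$levels, c("1", "2", "1", "1", "2", "1"))
  out2 <- train_model(m, x, y, x, y,
                      config = train_config(epochs = 5, batch_size = 2,
                                            batches_per_epoch = 2, seed = 20,
                                            lr = 0),
                      schedule = schedule_spec("coarse_to_fine", patience = 2))
  # with lr 0 nothing improves after the first record, so the phase gate
  # advances once `patience` stagnant epochs accumulate
  expect_equal(out2$history$levels, c("2", "2", "2", "2+1", "2+1"))
})
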