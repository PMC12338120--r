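# Independent oracles and shared fixtures for the test suite.

# brute-force minimum assignment cost: every injective map of rows to columns
brute_force_assignment <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  stopifnot(nr <= nc, nr <= 6)
  best <- Inf
  cols <- utils::combn(nc, nr, simplify = FALSE)
  perms <- perms_of(nr)
  for (cs in cols) for (p in perms) {
    v <- sum(cost[cbind(seq_len(nr), cs[p])])
    if (v < best) best <- v
  }
  best
}

perms_of <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in perms_of(n - 1L)) {
      rest <- setdiff(seq_len(n), i)
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

# random symmetric unweighted graph Laplacian (A - D sign), connected not
# required for distance arithmetic
random_laplacian <- function(n, p = 0.5) {
  A <- matrix(stats::rbinom(n * n, 1, p), n)
  A[lower.tri(A, diag = TRUE)] <- 0
  A <- A + t(A)
  A - diag(rowSums(A))
}

# random column-orthonormal matrix via QR
random_stiefel <- function(nrow, ncol) {
  qr.Q(qr(matrix(stats::rnorm(nrow * ncol), nrow, ncol)))[, seq_len(ncol),
                                                          drop = FALSE]
}

# hand-rolled dense GCN member forward, written with explicit per-node loops
# (independent of the package's vectorized implementation)
oracle_member_forward <- function(Z, X, params) {
  Z <- as.matrix(Z)
  n <- nrow(X)
  H <- X; hs <- list()
  for (ly in params$gcn) {
    A <- matrix(0, n, ncol(ly$W))
    ZH <- matrix(0, n, ncol(H))
    for (i in seq_len(n)) for (j in seq_len(ncol(H)))
      ZH[i, j] <- sum(Z[i, ] * H[, j])
    for (i in seq_len(n)) for (j in seq_len(ncol(ly$W)))
      A[i, j] <- sum(ZH[i, ] * ly$W[, j]) + ly$b[j]
    H <- ifelse(A > 0, A, 0)
    hs[[length(hs) + 1]] <- H
  }
  H <- do.call(cbind, hs)
  nd <- length(params$dense)
  for (l in seq_len(nd)) {
    ly <- params$dense[[l]]
    A <- matrix(0, n, ncol(ly$W))
    for (i in seq_len(n)) for (j in seq_len(ncol(ly$W)))
      A[i, j] <- sum(H[i, ] * ly$W[, j]) + ly$b[j]
    H <- if (l < nd) 1 / (1 + exp(-A)) else A
  }
  H
}

# desk dataset shared across test files; generated once per test run
desk_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_dataset_desk(seed = 1)
    cache
  }
})

# small toy dataset on a 4-ring tube for fast training tests
tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      geom <- build_lattice_geometry(tube_spec(4, 13, 3), resting = "geometry")
      grid <- list(LatAssoc = c(3, 57), LongAssoc = 30, LatAngle = c(3, 57),
                   LongAngle = 30, QuadAngles = "LatAngle")
      cfg <- sim_config_desk(n_nodes = 52, seed = 7, ramp_steps = 400,
                             hold_steps = 800, save_interval = 100)
      cache <<- generate_dataset(geom, grid, cfg)
    }
    cache
  }
})
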