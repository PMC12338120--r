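#' Training configuration
#'
#' Defaults follow the study protocol: batches of 8 frames, 1000 epochs of 20
#' batches each, Adam with default hyperparameters, a 90/10 train/validation
#' split over frames drawn with the run-level seed (so the split and batch
#' order are reproducible across models).
#'
#' @param batch_size Frames per batch.
#' @param epochs Number of training events (epochs).
#' @param batches_per_epoch Batches per epoch.
#' @param lr,beta1,beta2,eps Adam hyperparameters.
#' @param seed Run-level integer seed.
#' @param validation_fraction Fraction of frames held out for validation.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 8, epochs = 1000,
                         batches_per_epoch = 20, lr = 1e-3, beta1 = 0.9,
                         beta2 = 0.999, eps = 1e-7, seed = 42,
                         validation_fraction = 0.1) {
  stopifnot(batch_size >= 1, epochs >= 1, batches_per_epoch >= 1,
            validation_fraction > 0, validation_fraction < 1)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 batches_per_epoch = as.integer(batches_per_epoch),
                 lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
                 seed = as.integer(seed),
                 validation_fraction = validation_fraction),
            class = "train_config")
}

#' Per-(node, feature) normalization statistics from the training split
#'
#' Means and standard deviations are taken along the frame axis of the
#' training tensors only, and then applied to training and validation data
#' alike.  Standard deviations of constant features are floored at 1e-8 (with
#' a warning) so the transform stays invertible.
#'
#' @param x Input tensor, `frames x nodes x features`.
#' @param y Target matrix, `frames x nodes`.
#' @return A `norm_stats` object (`x_mean`, `x_sd`, `y_mean`, `y_sd`).
#' @export
normalize_stats <- function(x, y) {
  x_mean <- apply(x, c(2, 3), mean)
  x_sd <- apply(x, c(2, 3), stats::sd)
  y_mean <- colMeans(y)
  y_sd <- apply(y, 2, stats::sd)
  nfloor <- sum(x_sd < 1e-8) + sum(y_sd < 1e-8)
  if (nfloor > 0)
    warning(nfloor, " constant feature(s): standard deviation floored at 1e-8")
  x_sd[x_sd < 1e-8] <- 1e-8
  y_sd[y_sd < 1e-8] <- 1e-8
  structure(list(x_mean = x_mean, x_sd = x_sd, y_mean = y_mean, y_sd = y_sd),
            class = "norm_stats")
}

#' Apply / invert normalization
#' @param x Input tensor (`frames x nodes x features`) or `NULL`.
#' @param y Target matrix (`frames x nodes`) or `NULL`.
#' @param stats A `norm_stats`.
#' @param invert If `TRUE`, undo the transform.
#' @return List with normalized (or restored) `x` and `y`.
#' @export
apply_normalization <- function(x = NULL, y = NULL, stats, invert = FALSE) {
  out <- list()
  if (!is.null(x)) {
    xs <- x
    for (f in seq_len(dim(x)[1])) {
      xs[f, , ] <- if (invert) x[f, , ] * stats$x_sd + stats$x_mean
                   else (x[f, , ] - stats$x_mean) / stats$x_sd
    }
    out$x <- xs
  }
  if (!is.null(y)) {
    out$y <- if (invert) sweep(sweep(y, 2, stats$y_sd, "*"), 2, stats$y_mean, "+")
             else sweep(sweep(y, 2, stats$y_mean, "-"), 2, stats$y_sd, "/")
  }
  out
}

#' Normalized mean squared error
#'
#' Mean squared difference between prediction and target, averaged over all
#' nodes and frames, with both signals standardized by training-split
#' statistics.  If `stats` is omitted the inputs are assumed to be already
#' normalized.  Unitless; an uninformative all-zero predictor scores about 1
#' on unit-variance targets.
#'
#' @param pred,target Matrices of matching shape (`frames x nodes`).
#' @param stats Optional `norm_stats` used to normalize both arguments.
#' @return Non-negative scalar.
#' @export
nmse <- function(pred, target, stats = NULL) {
  if (!is.null(dim(pred)) && !is.null(dim(target)))
    stopifnot(all(dim(pred) == dim(target)))
  if (!is.null(stats)) {
    pred <- apply_normalization(y = pred, stats = stats)$y
    target <- apply_normalization(y = target, stats = stats)$y
  }
  mean((pred - target)^2)
}

# ---------------------------------------------------------------------------
# FLOP cost model

#' FLOP cost formulas
#'
#' The cost of a graph-convolution layer with `n x n` structure matrix `Z`
#' (`nnz_Z` nonzeros), `n x F` input and `F x C` filter is `n*F*(nnz_Z + C)`;
#' a node-wise dense layer costs `n*F*C`; a general matrix product of an
#' `n x k` by a `k x m` matrix costs `n*k*m`.  Constants are taken exactly as
#' these products (no hidden multiply-add factors).
#'
#' @param n Nodes. @param F_in Input feature width. @param nnz_Z Nonzeros of
#'   the structure matrix. @param C Output feature width.
#' @return FLOP count (numeric).
#' @export
flops_gcn_layer <- function(n, F_in, nnz_Z, C) {
  stopifnot(n > 0, F_in > 0, nnz_Z > 0, C > 0)
  n * F_in * (nnz_Z + C)
}

#' @rdname flops_gcn_layer
#' @export
flops_dense <- function(n, F_in, C) n * F_in * C

#' @rdname flops_gcn_layer
#' @param m,k General matmul dimensions (`n x k` times `k x m`).
#' @export
flops_matmul <- function(n, m, k) n * m * k

# forward FLOPs of one member on one frame
flops_member_forward <- function(spec, n, nnz_Z, input_dim) {
  tot <- 0; fin <- input_dim
  for (f in spec$gcn_filters) {
    tot <- tot + flops_gcn_layer(n, fin, nnz_Z, f)
    fin <- f
  }
  fin <- sum(spec$gcn_filters)
  for (f in spec$dense_filters) {
    tot <- tot + flops_dense(n, fin, f)
    fin <- f
  }
  tot
}

#' FLOP ledger for one training event
#'
#' Per frame, the ledger prices the forward pass of every member (the full
#' ensemble defines the loss), the restriction/prolongation products, and the
#' backward pass of the components updated during the event.  Backpropagation
#' through a component is priced at twice its forward cost (one transposed
#' aggregation product plus one weight-gradient product per layer).  The
#' event total is `per-frame cost x batch_size x batches_per_epoch`.
#'
#' @param model A `gcn_model`.
#' @param levels Integer vector of member indices updated during the event
#'   (`seq_along(members)` for a joint epoch).
#' @param config A [train_config()].
#' @return List with `total` and a per-component `breakdown`.
#' @export
flops_event <- function(model, levels, config) {
  nmem <- length(model$members)
  n_fine <- nrow(model$Z[[1]])
  sizes <- vapply(model$Z, nrow, 1L)
  nnzs <- vapply(model$Z, nnz, 1)
  Fdim <- model$input_dim
  fwd <- vapply(seq_len(nmem), function(i)
    flops_member_forward(model$specs[[i]], sizes[i], nnzs[i], Fdim), 1)
  proj <- numeric(nmem)
  if (model$kind %in% c("gpcn", "agpcn")) {
    for (i in seq_len(nmem)[-1]) {
      proj[i] <- flops_matmul(sizes[i], Fdim, n_fine) +   # restrict input
        flops_matmul(n_fine, 1, sizes[i])                 # prolong output
    }
  } else if (model$kind == "diffpool") {
    for (i in seq_len(nmem)[-1]) {
      np <- sizes[i - 1]; nc <- sizes[i]
      proj[i] <- flops_gcn_layer(np, Fdim, nnzs[i - 1], nc) +  # aux logits
        flops_matmul(nc, Fdim, np) +                           # t(S) X
        flops_matmul(np, nc, np) + flops_matmul(nc, nc, np) +  # t(S) Z S
        flops_matmul(n_fine, 1, sizes[i])                      # upsample
    }
  }
  bwd <- numeric(nmem)
  bwd[levels] <- 2 * (fwd[levels] + proj[levels])
  frames <- config$batch_size * config$batches_per_epoch
  breakdown <- data.frame(member = seq_len(nmem), forward = fwd,
                          projection = proj, backward = bwd)
  list(total = frames * sum(fwd + proj + bwd), breakdown = breakdown,
       per_frame = sum(fwd + proj + bwd))
}

# ---------------------------------------------------------------------------
# Schedules

#' Training schedule specification
#'
#' `"joint"` updates every level each epoch.  `"mu_cycle"` unrolls the
#' multigrid recursion `cycle(l) = [l] + gamma * cycle(l+1) + [l]` (coarsest
#' level: `[l]`; `gamma = 0` degenerates to fine-only), starting at the
#' finest level, and repeats cycles until the epoch budget is spent;
#' `gamma = 1` is a V-cycle.  `"coarse_to_fine"` trains the coarsest level
#' alone, then coarsest+middle, then all levels, advancing a phase after
#' `patience` epochs without validation improvement.
#'
#' @param kind One of `"joint"`, `"mu_cycle"`, `"coarse_to_fine"`.
#' @param gamma Recursion parameter in `{0,1,2,3}` (mu_cycle only).
#' @param patience Epochs without improvement before a phase advances.
#' @return A `schedule_spec`.
#' @export
schedule_spec <- function(kind = c("joint", "mu_cycle", "coarse_to_fine"),
                          gamma = NULL, patience = 10) {
  kind <- match.arg(kind)
  if (kind == "mu_cycle") {
    if (is.null(gamma) || !gamma %in% 0:3)
      stop("invalid spec: gamma must be in {0,1,2,3} for mu_cycle schedules")
  } else if (!is.null(gamma)) {
    stop("gamma is only meaningful for mu_cycle schedules")
  }
  structure(list(kind = kind, gamma = if (is.null(gamma)) NULL else as.integer(gamma),
                 patience = as.integer(patience)),
            class = "schedule_spec")
}

#' Unroll a training schedule into level events
#'
#' Returns the ordered list of per-epoch trainable level sets for one cycle
#' (mu_cycle), a single all-levels event (joint), or the phase list
#' (coarse_to_fine; attribute `"gated"` marks patience gating).  Level 1 is
#' the finest.
#'
#' @param n_levels Number of hierarchy levels (>= 1).
#' @param spec A [schedule_spec()].
#' @return List of integer vectors (levels updated in each event).
#' @export
schedule_sequence <- function(n_levels, spec) {
  stopifnot(n_levels >= 1)
  if (spec$kind == "joint") return(list(seq_len(n_levels)))
  if (spec$kind == "coarse_to_fine") {
    phases <- lapply(seq_len(n_levels), function(p) n_levels - seq_len(p) + 1L)
    attr(phases, "gated") <- TRUE
    return(phases)
  }
  gamma <- spec$gamma
  cyc <- function(l) {
    if (l == n_levels || gamma == 0) return(list(l))
    c(list(l), do.call(c, rep(cyc(l + 1), gamma)), list(l))
  }
  lapply(cyc(1L), as.integer)
}

# ---------------------------------------------------------------------------
# Parameter flattening and Adam

flatten_params <- function(model) {
  out <- list()
  for (i in seq_along(model$members)) {
    mp <- model$members[[i]]
    for (l in seq_along(mp$gcn)) {
      out[[sprintf("m%d.gcn%d.W", i, l)]] <- mp$gcn[[l]]$W
      out[[sprintf("m%d.gcn%d.b", i, l)]] <- mp$gcn[[l]]$b
    }
    for (l in seq_along(mp$dense)) {
      out[[sprintf("m%d.dense%d.W", i, l)]] <- mp$dense[[l]]$W
      out[[sprintf("m%d.dense%d.b", i, l)]] <- mp$dense[[l]]$b
    }
  }
  if (model$kind == "agpcn")
    for (i in seq_along(model$pairwise_P))
      out[[sprintf("P%d", i)]] <- model$pairwise_P[[i]]
  if (model$kind == "diffpool")
    for (i in seq_along(model$pool_aux)) {
      out[[sprintf("pool%d.W", i)]] <- model$pool_aux[[i]]$W
      out[[sprintf("pool%d.b", i)]] <- model$pool_aux[[i]]$b
    }
  out
}

set_params <- function(model, flat) {
  for (nm in names(flat)) {
    v <- flat[[nm]]
    if (grepl("^m[0-9]+\\.", nm)) {
      parts <- strsplit(nm, "\\.")[[1]]
      i <- as.integer(sub("m", "", parts[1]))
      grp <- sub("[0-9]+$", "", parts[2])
      l <- as.integer(sub("^(gcn|dense)", "", parts[2]))
      model$members[[i]][[grp]][[l]][[parts[3]]] <- v
    } else if (grepl("^P[0-9]+$", nm)) {
      model$pairwise_P[[as.integer(sub("P", "", nm))]] <- v
    } else if (grepl("^pool", nm)) {
      parts <- strsplit(nm, "\\.")[[1]]
      i <- as.integer(sub("pool", "", parts[1]))
      model$pool_aux[[i]][[parts[2]]] <- v
    }
  }
  model
}

# names of parameters trainable during an event updating `levels`
trainable_names <- function(model, levels) {
  nms <- character(0)
  for (i in levels)
    nms <- c(nms, sprintf("m%d.", i))
  pat <- paste0("^(", paste(gsub("\\.", "\\\\.", nms), collapse = "|"), ")")
  flat <- names(flatten_params(model))
  sel <- grepl(pat, flat)
  if (model$kind == "agpcn") sel <- sel | grepl("^P[0-9]+$", flat)
  if (model$kind == "diffpool") sel <- sel | grepl("^pool", flat)
  flat[sel]
}

adam_init <- function(flat) {
  list(m = lapply(flat, function(v) v * 0),
       v = lapply(flat, function(v) v * 0),
       t = 0L)
}

adam_step <- function(flat, grads, state, cfg, which_names) {
  state$t <- state$t + 1L
  b1 <- cfg$beta1; b2 <- cfg$beta2
  corr1 <- 1 - b1^state$t; corr2 <- 1 - b2^state$t
  for (nm in which_names) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (is.null(dim(flat[[nm]]))) g <- as.numeric(g)
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mh <- state$m[[nm]] / corr1
    vh <- state$v[[nm]] / corr2
    flat[[nm]] <- flat[[nm]] - cfg$lr * mh / (sqrt(vh) + cfg$eps)
  }
  list(flat = flat, state = state)
}

# ---------------------------------------------------------------------------
# Tape construction for a batch

member_tape <- function(tp, Zmul, x_id, pids, spec, i) {
  hidden <- integer(0)
  h <- x_id
  for (l in seq_along(spec$gcn_filters)) {
    t1 <- Zmul(tp, h)
    t2 <- tp_matmul(tp, t1, pids[[sprintf("m%d.gcn%d.W", i, l)]])
    a <- tp_add_bias(tp, t2, pids[[sprintf("m%d.gcn%d.b", i, l)]])
    h <- tp_relu(tp, a)
    hidden <- c(hidden, h)
  }
  h <- tp_cbind(tp, as.list(hidden))
  nd <- length(spec$dense_filters)
  for (l in seq_len(nd)) {
    t2 <- tp_matmul(tp, h, pids[[sprintf("m%d.dense%d.W", i, l)]])
    a <- tp_add_bias(tp, t2, pids[[sprintf("m%d.dense%d.b", i, l)]])
    h <- if (l < nd) tp_sigmoid(tp, a) else a
  }
  h
}

# builds loss tape; returns list(tp, loss, pids) where pids maps parameter
# names to node ids.  `active` restricts which members go on the tape (the
# others' fine-scale contributions must then be supplied as the constant
# matrix `const_offset`); adaptive and DiffPool models always tape every
# member because their projections are themselves trainable.
build_loss_tape <- function(model, Xstack, ystack, B, Zbdiag,
                            active = NULL, const_offset = NULL) {
  tp <- tape_new()
  flat <- flatten_params(model)
  pids <- lapply(flat, function(v) tp_const(tp, v))
  x_id <- tp_const(tp, Xstack)
  nmem <- length(model$members)
  kind <- model$kind
  if (is.null(active) || kind %in% c("agpcn", "diffpool"))
    active <- seq_len(nmem)

  struct_mul <- function(i) {
    Zb <- Zbdiag[[i]]
    function(tp, h) tp_struct_mul(tp, Zb, h)
  }

  if (kind %in% c("ensemble", "ngcn")) {
    outs <- lapply(active, function(i)
      member_tape(tp, struct_mul(i), x_id, pids, model$specs[[i]], i))
    if (!is.null(const_offset))
      outs <- c(outs, list(tp_const(tp, const_offset)))
    pred <- tp_add(tp, outs)
  } else if (kind %in% c("gpcn", "agpcn")) {
    Pn <- lapply(seq_along(model$pairwise_P), function(i)
      pids[[sprintf("P%d", i)]])
    if (kind == "gpcn")
      Pn <- lapply(model$pairwise_P, function(P) tp_const(tp, P))
    # composed projections as tape products
    comp <- vector("list", nmem)
    for (i in seq_len(nmem - 1))
      comp[[i + 1]] <- if (i == 1) Pn[[1]] else tp_matmul(tp, comp[[i]], Pn[[i]])
    outs <- list()
    for (i in active) {
      if (i == 1) {
        outs <- c(outs, list(member_tape(tp, struct_mul(1), x_id, pids,
                                         model$specs[[1]], 1)))
      } else {
        xi <- tp_block_proj(tp, comp[[i]], x_id, B, transpose = TRUE)
        oi <- member_tape(tp, struct_mul(i), xi, pids, model$specs[[i]], i)
        outs <- c(outs, list(tp_block_proj(tp, comp[[i]], oi, B,
                                           transpose = FALSE)))
      }
    }
    if (!is.null(const_offset))
      outs <- c(outs, list(tp_const(tp, const_offset)))
    pred <- tp_add(tp, outs)
  } else if (kind == "diffpool") {
    outs <- vector("list", nmem)
    outs[[1]] <- member_tape(tp, struct_mul(1), x_id, pids, model$specs[[1]], 1)
    # stacked fine Z for the pair ops
    Zfine <- as.matrix(model$Z[[1]])
    zstack <- tp_const(tp, do.call(rbind, rep(list(Zfine), B)))
    xcur <- x_id
    Ss <- list()
    for (i in seq_len(nmem)[-1]) {
      lg1 <- tp_block_pair_mul(tp, zstack, xcur, B)
      lg2 <- tp_matmul(tp, lg1, pids[[sprintf("pool%d.W", i - 1)]])
      lg <- tp_add_bias(tp, lg2, pids[[sprintf("pool%d.b", i - 1)]])
      S <- tp_row_softmax(tp, lg)
      xcur <- tp_block_restrict(tp, S, xcur, B)
      zstack <- tp_block_coarsen_pair(tp, S, zstack, B)
      Ss[[length(Ss) + 1]] <- S
      pair_mul <- function(zs) function(tp, h) tp_block_pair_mul(tp, zs, h, B)
      oi <- member_tape(tp, pair_mul(zstack), xcur, pids, model$specs[[i]], i)
      for (j in rev(seq_along(Ss))) oi <- tp_block_upsample(tp, Ss[[j]], oi, B)
      outs[[i]] <- oi
    }
    pred <- tp_add(tp, outs)
  }
  loss <- tp_mse(tp, pred, ystack)
  list(tp = tp, loss = loss, pred = pred, pids = pids, x_id = x_id)
}

stack_frames <- function(x, idx) {
  do.call(rbind, lapply(idx, function(f) x[f, , , drop = TRUE]))
}

# fine-scale contribution of member i on one frame (projection included)
member_contribution <- function(model, i, X, comp = NULL) {
  if (model$kind %in% c("gpcn", "agpcn") && i > 1) {
    P <- comp[[i]]
    as.numeric(P %*% member_forward(model$Z[[i]], crossprod(P, X),
                                    model$members[[i]]))
  } else {
    as.numeric(member_forward(model$Z[[i]], X, model$members[[i]]))
  }
}

# per-frame forward FLOPs of member i including its projections
member_frame_flops <- function(model, i) {
  sizes <- vapply(model$Z, nrow, 1L)
  f <- flops_member_forward(model$specs[[i]], sizes[i], nnz(model$Z[[i]]),
                            model$input_dim)
  if (model$kind %in% c("gpcn", "agpcn", "diffpool") && i > 1)
    f <- f + flops_matmul(sizes[i], model$input_dim, sizes[1]) +
      flops_matmul(sizes[1], 1, sizes[i])
  f
}

#' Predict per-node energies for a tensor of frames
#' @param model A `gcn_model`.
#' @param x Input tensor `frames x nodes x features` (normalized space).
#' @return Matrix `frames x nodes` of predictions (normalized space).
#' @export
model_predict <- function(model, x) {
  nf <- dim(x)[1]
  t(vapply(seq_len(nf), function(f)
    as.numeric(model_forward(model, x[f, , , drop = TRUE])),
    numeric(dim(x)[2])))
}

#' Train a model on a normalized frame dataset
#'
#' Mean-squared-error loss at the fine scale.  One event = one epoch of
#' `batches_per_epoch` batches; an event updates only its levels' member
#' parameters (all levels for joint training; prolongations and pooling
#' parameters are always updated when the model is adaptive/DiffPool), while
#' the full-ensemble prediction defines the loss.  Because a frozen member's
#' fine-scale contribution is constant during an event, it is computed once
#' per frame and cached (the trained level effectively fits the residual);
#' caches are invalidated when their member — or, for adaptive models, any
#' projection — changes.  Batches are drawn by shuffling the training frames
#' each epoch without replacement (reshuffling when exhausted).  The history
#' records cumulative ledger FLOPs for the computations actually performed
#' (cached contributions are priced once) and the running-minimum validation
#' NMSE.
#'
#' @param model A `gcn_model`.
#' @param x,y Normalized training tensor (`frames x n x F`) and targets
#'   (`frames x n`).
#' @param val_x,val_y Normalized validation split.
#' @param config A [train_config()].
#' @param schedule A [schedule_spec()].
#' @return List `model` (trained), `history` (data.frame with `epoch`,
#'   `levels`, `cum_flops`, `train_mse`, `val_nmse`, `min_val_nmse`).
#' @export
train_model <- function(model, x, y, val_x, val_y, config = train_config(),
                        schedule = schedule_spec("joint")) {
  set.seed(config$seed)
  nmem <- length(model$members)
  n_nodes <- dim(x)[2]
  ntrain <- dim(x)[1]
  B <- config$batch_size
  Zbdiag <- lapply(model$Z, function(Z)
    methods::as(Matrix::bdiag(rep(list(Z), B)), "CsparseMatrix"))

  flat <- flatten_params(model)
  opt <- adam_init(flat)
  events <- schedule_sequence(nmem, schedule)
  gated <- isTRUE(attr(events, "gated"))

  hist <- vector("list", config$epochs)
  pool <- sample(ntrain)
  pos <- 1L
  draw_batch <- function() {
    if (pos + B - 1L > length(pool)) { pool <<- sample(ntrain); pos <<- 1L }
    idx <- pool[pos:(pos + B - 1L)]
    pos <<- pos + B
    idx
  }

  cum_flops <- 0
  min_val <- Inf
  phase <- 1L; since_best <- 0L; phase_best <- Inf
  ev_i <- 0L

  # fine-scale contribution cache for frozen members: valid while a member's
  # parameters (and all projections) stay fixed.  Adaptive and DiffPool
  # models retrain their projections every event, so they never cache.
  can_cache <- model$kind %in% c("gpcn", "ensemble", "ngcn")
  cache_valid <- matrix(FALSE, ntrain, nmem)
  cache_val <- vector("list", nmem)
  for (i in seq_len(nmem)) cache_val[[i]] <- matrix(0, ntrain, n_nodes)

  for (epoch in seq_len(config$epochs)) {
    if (gated) {
      levels <- events[[phase]]
    } else {
      ev_i <- ev_i %% length(events) + 1L
      levels <- events[[ev_i]]
    }
    train_nms <- trainable_names(model, levels)
    frozen <- if (can_cache && length(levels) < nmem)
      setdiff(seq_len(nmem), levels) else integer(0)
    active <- setdiff(seq_len(nmem), frozen)
    comp <- if (model$kind %in% c("gpcn", "agpcn"))
      composed_projections(model$pairwise_P, vapply(model$Z, nrow, 1L))
    else NULL
    losses <- numeric(config$batches_per_epoch)
    ev_flops <- 0
    for (bt in seq_len(config$batches_per_epoch)) {
      idx <- draw_batch()
      Xs <- stack_frames(x, idx)
      ys <- matrix(as.numeric(t(y[idx, , drop = FALSE])), ncol = 1)
      const_offset <- NULL
      if (length(frozen)) {
        const_offset <- matrix(0, B * n_nodes, 1)
        for (i in frozen) {
          for (b in seq_along(idx)) {
            f <- idx[b]
            if (!cache_valid[f, i]) {
              cache_val[[i]][f, ] <-
                member_contribution(model, i, x[f, , , drop = TRUE], comp)
              cache_valid[f, i] <- TRUE
              ev_flops <- ev_flops + member_frame_flops(model, i)
            }
            rows <- ((b - 1) * n_nodes + 1):(b * n_nodes)
            const_offset[rows, 1] <- const_offset[rows, 1] + cache_val[[i]][f, ]
          }
        }
      }
      tl <- build_loss_tape(model, Xs, ys, B, Zbdiag, active = active,
                            const_offset = const_offset)
      losses[bt] <- tp_value(tl$tp, tl$loss)
      if (!is.finite(losses[bt]))
        stop("training diverged: non-finite loss at epoch ", epoch)
      grads_all <- tape_backward(tl$tp, tl$loss)
      grads <- lapply(tl$pids, function(id) grads_all[[id]])
      upd <- adam_step(flat, grads, opt, config, train_nms)
      flat <- upd$flat; opt <- upd$state
      model <- set_params(model, flat)
      # trained members: forward plus backward (2x forward) per frame
      ev_flops <- ev_flops + 3 * B * sum(vapply(active, function(i)
        member_frame_flops(model, i), 1))
    }
    # members updated this event lose their cached contributions
    cache_valid[, levels] <- FALSE
    if (model$kind == "agpcn") cache_valid[] <- FALSE
    cum_flops <- cum_flops + ev_flops
    pv <- model_predict(model, val_x)
    val_nmse <- nmse(pv, val_y)
    min_val <- min(min_val, val_nmse)
    hist[[epoch]] <- data.frame(epoch = epoch,
                                levels = paste(levels, collapse = "+"),
                                cum_flops = cum_flops,
                                train_mse = mean(losses),
                                val_nmse = val_nmse,
                                min_val_nmse = min_val)
    if (gated) {
      if (val_nmse < phase_best - 1e-12) {
        phase_best <- val_nmse; since_best <- 0L
      } else since_best <- since_best + 1L
      if (since_best >= schedule$patience && phase < length(events)) {
        phase <- phase + 1L; since_best <- 0L; phase_best <- Inf
      }
    }
  }
  list(model = model, history = do.call(rbind, hist))
}

#' Write a training history to CSV
#' @param history Data frame from [train_model()].
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_history <- function(history, file) {
  utils::write.csv(history, file, row.names = FALSE)
  invisible(file)
}
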