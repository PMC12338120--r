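#' Generic graph-convolution forward pass
#'
#' Applies `X_m = g_m(Z %*% X_{m-1} %*% W_m + b_m)` layer by layer, with the
#' bias row-vector broadcast across nodes.  The structure matrix `Z` is the
#' raw graph Laplacian in the `A - D` convention (no normalization, no
#' self-loop augmentation).
#'
#' @param Z Structure matrix (`n x n`).
#' @param X Node-feature matrix (`n x F`).
#' @param layers List of layers, each `list(W, b, activation)` with
#'   `activation` one of `"relu"`, `"sigmoid"`, `"linear"`.
#' @return Node-feature matrix after the last layer.
#' @export
gcn_forward <- function(Z, X, layers) {
  if (nrow(X) != nrow(Z)) stop("X must have one row per node of Z")
  H <- X
  for (ly in layers) {
    if (ncol(H) != nrow(ly$W))
      stop(sprintf("feature-width mismatch: %d features into a %d-input layer",
                   ncol(H), nrow(ly$W)))
    A <- as.matrix(Z %*% H %*% ly$W)
    A <- sweep(A, 2, ly$b, "+")
    H <- activate(A, ly$activation)
  }
  H
}

activate <- function(A, kind) {
  switch(kind,
         relu = pmax(A, 0),
         sigmoid = 1 / (1 + exp(-A)),
         linear = A,
         stop("unknown activation: ", kind))
}

#' Specify one ensemble member network
#'
#' A member is a stack of ReLU graph-convolution layers whose outputs are
#' concatenated node-wise and fed to a node-wise dense head (sigmoid hidden
#' layers, linear scalar output).
#'
#' @param gcn_filters Integer vector of GCN layer widths.
#' @param dense_filters Integer vector of dense head widths, ending in 1.
#' @return A `member_spec`.
#' @export
member_spec <- function(gcn_filters, dense_filters = c(256, 32, 8, 1)) {
  gcn_filters <- as.integer(gcn_filters)
  dense_filters <- as.integer(dense_filters)
  stopifnot(length(gcn_filters) >= 1, all(gcn_filters > 0),
            length(dense_filters) >= 1, all(dense_filters > 0))
  if (dense_filters[length(dense_filters)] != 1)
    stop("the last dense width must be 1 (per-node scalar output)")
  structure(list(gcn_filters = gcn_filters, dense_filters = dense_filters),
            class = "member_spec")
}

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

# Glorot-uniform parameter initialization for one member; uses the current
# RNG stream (callers seed at run level).
init_member_params <- function(spec, input_dim) {
  gcn <- list(); fin <- input_dim
  for (f in spec$gcn_filters) {
    gcn[[length(gcn) + 1]] <- list(W = glorot(fin, f), b = numeric(f))
    fin <- f
  }
  dense <- list(); fin <- sum(spec$gcn_filters)
  for (f in spec$dense_filters) {
    dense[[length(dense) + 1]] <- list(W = glorot(fin, f), b = numeric(f))
    fin <- f
  }
  list(gcn = gcn, dense = dense)
}

#' Forward pass of one ensemble member
#'
#' ReLU GCN stack; node-wise concatenation of every GCN layer's output; then
#' the dense head applied node-wise (sigmoid hidden layers, linear output
#' layer).
#'
#' @param Z Structure matrix for this member's level.
#' @param X Node features at this level.
#' @param params Parameter list from the model (fields `gcn`, `dense`).
#' @return `n x 1` matrix of per-node scalar predictions.
#' @export
member_forward <- function(Z, X, params) {
  H <- X; hidden <- list()
  for (ly in params$gcn) {
    A <- sweep(as.matrix(Z %*% H %*% ly$W), 2, ly$b, "+")
    H <- pmax(A, 0)
    hidden[[length(hidden) + 1]] <- H
  }
  H <- do.call(cbind, hidden)
  nd <- length(params$dense)
  for (i in seq_len(nd)) {
    ly <- params$dense[[i]]
    A <- sweep(H %*% ly$W, 2, ly$b, "+")
    H <- if (i < nd) 1 / (1 + exp(-A)) else A
  }
  H
}

#' Construct a (multi-member) GCN model
#'
#' One constructor covers the whole model family compared in this package:
#' \describe{
#'   \item{`"gpcn"` / `"agpcn"`}{Multiscale ensemble over a hierarchy: the
#'     fine member sees `X`; member `i >= 2` sees `t(P[1,i]) %*% X` on its
#'     level's Laplacian and its output is mapped back with `P[1,i]`; outputs
#'     are summed at the fine scale.  `"agpcn"` additionally treats the
#'     pairwise prolongation matrices as trainable parameters (orthogonally
#'     initialized, unconstrained afterwards).}
#'   \item{`"ensemble"`}{Plain sum of members, all on the fine Laplacian.}
#'   \item{`"ngcn"`}{One member per neighborhood radius `r`, using `Z^r` as
#'     its structure matrix.}
#'   \item{`"diffpool"`}{Mirrors the hierarchy topology, but each projection
#'     is the row-softmaxed output of an auxiliary GCN (a pooling assignment)
#'     and coarse structure matrices are `t(S) Z S`.}
#' }
#'
#' @param kind Model kind, see above.
#' @param members List of [member_spec()]s, fine level first.
#' @param hierarchy A `gpcn_hierarchy` (gpcn/agpcn/diffpool kinds).
#' @param graph Fine `lattice_graph` or Laplacian (ensemble/ngcn kinds).
#' @param radii Integer vector of neighborhood radii (ngcn).
#' @param input_dim Number of input features per node.
#' @param seed Integer seed for Glorot-uniform initialization.
#' @return A `gcn_model` with fields `members` (parameters), `Z` (structure
#'   matrices per member), `P` (composed projections, gpcn), `pairwise_P`
#'   (trainable, agpcn), `pool_aux` (diffpool auxiliary GCNs).
#' @export
gcn_model <- function(kind = c("gpcn", "agpcn", "ensemble", "ngcn", "diffpool"),
                      members, hierarchy = NULL, graph = NULL, radii = NULL,
                      input_dim = 10, seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  members <- lapply(members, function(m)
    if (inherits(m, "member_spec")) m else do.call(member_spec, m))
  model <- list(kind = kind, specs = members, input_dim = input_dim)

  if (kind %in% c("gpcn", "agpcn", "diffpool")) {
    stopifnot(inherits(hierarchy, "gpcn_hierarchy"),
              length(members) == length(hierarchy$sizes))
    model$hierarchy <- hierarchy
    model$Z <- hierarchy$laplacians
    model$sizes <- hierarchy$sizes
    if (kind == "diffpool") {
      # one auxiliary single-layer GCN per coarsening step, output = n_next
      model$pool_aux <- lapply(seq_len(length(members) - 1), function(i)
        list(W = glorot(input_dim, hierarchy$sizes[i + 1]),
             b = numeric(hierarchy$sizes[i + 1])))
    } else {
      model$pairwise_P <- lapply(hierarchy$pairwise, function(m) m$P)
    }
  } else {
    stopifnot(!is.null(graph))
    Zf <- if (inherits(graph, "lattice_graph")) laplacian(graph) else graph
    if (kind == "ngcn") {
      stopifnot(!is.null(radii), all(radii >= 1),
                length(radii) == length(members))
      model$radii <- as.integer(radii)
      model$Z <- lapply(radii, function(r) matpow(Zf, r))
    } else {
      model$Z <- rep(list(Zf), length(members))
    }
  }
  model$members <- lapply(seq_along(members), function(i)
    init_member_params(members[[i]], input_dim))
  structure(model, class = "gcn_model")
}

matpow <- function(Z, r) {
  Zs <- methods::as(Matrix::Matrix(Z, sparse = TRUE), "CsparseMatrix")
  out <- Zs
  for (i in seq_len(r - 1)) out <- out %*% Zs
  out
}

# composed fine-to-level projections P[1,i] from the pairwise list
composed_projections <- function(pairwise_P, sizes) {
  k <- length(sizes)
  composed <- vector("list", k)
  acc <- NULL
  for (i in seq_len(k - 1)) {
    acc <- if (is.null(acc)) pairwise_P[[i]] else acc %*% pairwise_P[[i]]
    composed[[i + 1]] <- acc
  }
  composed
}

#' Ensemble forward pass at the fine scale
#'
#' Evaluates the full model on one frame: fine member plus the prolonged
#' coarse-member outputs (Eq.-style sum), or the plain/N-GCN/DiffPool
#' variants' member sums.
#'
#' @param model A `gcn_model`.
#' @param X Fine node-feature matrix (`n_fine x input_dim`).
#' @return `n_fine x 1` matrix of per-node predictions.
#' @export
model_forward <- function(model, X) {
  kind <- model$kind
  if (kind %in% c("gpcn", "agpcn")) {
    P1 <- composed_projections(model$pairwise_P, model$sizes)
    out <- member_forward(model$Z[[1]], X, model$members[[1]])
    for (i in seq_along(model$members)[-1]) {
      Xi <- crossprod(P1[[i]], X)
      out <- out + P1[[i]] %*% member_forward(model$Z[[i]], Xi,
                                              model$members[[i]])
    }
    return(out)
  }
  if (kind == "diffpool") {
    out <- member_forward(model$Z[[1]], X, model$members[[1]])
    Zc <- model$Z[[1]]; Xc <- X; Sprod <- NULL
    for (i in seq_along(model$members)[-1]) {
      dp <- diffpool_coarsen(Zc, Xc, model$pool_aux[[i - 1]])
      Zc <- dp$Z_coarse; Xc <- dp$X_coarse
      Sprod <- if (is.null(Sprod)) dp$S else Sprod %*% dp$S
      out <- out + Sprod %*% member_forward(Zc, Xc, model$members[[i]])
    }
    return(out)
  }
  # ensemble / ngcn: sum of members on their structure matrices
  outs <- lapply(seq_along(model$members), function(i)
    member_forward(model$Z[[i]], X, model$members[[i]]))
  Reduce(`+`, outs)
}

#' Differentiable pooling coarsening step
#'
#' Computes the pooling assignment `S` as the row-softmax of an auxiliary
#' single-layer GCN's output (`n x n_coarse` logits), then returns the pooled
#' data `t(S) %*% X` and pooled structure matrix `t(S) %*% Z %*% S`.
#'
#' @param Z Structure matrix (`n x n`).
#' @param X Node features (`n x F`).
#' @param aux_params Auxiliary layer parameters `list(W, b)` with
#'   `ncol(W) = n_coarse < n`.
#' @return List `Z_coarse` (`n_c x n_c`), `X_coarse` (`n_c x F`), `S`
#'   (`n x n_c`, rows on the probability simplex).
#' @export
diffpool_coarsen <- function(Z, X, aux_params) {
  n <- nrow(Z); nc <- ncol(aux_params$W)
  if (nc >= n) stop("invalid spec: pooled size must be smaller than input")
  logits <- sweep(as.matrix(Z %*% X %*% aux_params$W), 2, aux_params$b, "+")
  M <- exp(logits - apply(logits, 1, max))
  S <- M / rowSums(M)
  ZS <- as.matrix(Z %*% S)
  list(Z_coarse = crossprod(S, ZS), X_coarse = crossprod(S, X), S = S)
}

#' N-GCN forward pass
#'
#' Sum of members where member `r` aggregates with the `r`-th power of the
#' structure matrix (neighborhood radius `r`).
#'
#' @param Z Fine structure matrix.
#' @param X Node features.
#' @param radii Integer radii (>= 1), one per member.
#' @param members List of member parameter sets.
#' @return Per-node predictions.
#' @export
ngcn_forward <- function(Z, X, radii, members) {
  stopifnot(length(radii) == length(members), all(radii >= 1))
  outs <- lapply(seq_along(radii), function(i)
    member_forward(matpow(Z, radii[i]), X, members[[i]]))
  Reduce(`+`, outs)
}

#' Model presets by architecture-table name
#'
#' Named filter configurations for the comparison experiments.  `"paper"`
#' scale is the reference configuration (GCN filters 64/32/16, dense head
#' 256-32-8-1); `"desk"` scale shrinks widths (16/12/8, head 32-8-1) for
#' laptop-sized runs.  Preset names: `"Single GCN"`, `"2-GCN Ensemble"`,
#' `"3-GCN Ensemble"`, `"2-level GPCN"`, `"3-level GPCN"`,
#' `"2-level A-GPCN"`, `"3-level A-GPCN"`, `"N-GCN (1,2,4)"`,
#' `"N-GCN (1,2,4,8,16)"`, `"DiffPool"`.
#'
#' @param name Preset name (see above).
#' @param scale `"desk"` or `"paper"`.
#' @return List with fields `kind`, `members`, and optionally `radii` /
#'   `levels`, consumable by [gpcn_fit()].
#' @export
model_preset <- function(name, scale = c("desk", "paper")) {
  scale <- match.arg(scale)
  w <- if (scale == "paper") c(64, 32, 16) else c(16, 12, 8)
  dh <- if (scale == "paper") c(256, 32, 8, 1) else c(32, 8, 1)
  m <- function(f) member_spec(rep(f, 3), dh)
  switch(name,
    "Single GCN" = list(kind = "ensemble", members = list(m(w[1]))),
    "2-GCN Ensemble" = list(kind = "ensemble", members = list(m(w[1]), m(w[2]))),
    "3-GCN Ensemble" = list(kind = "ensemble",
                            members = list(m(w[1]), m(w[2]), m(w[3]))),
    "2-level GPCN" = list(kind = "gpcn", levels = 2,
                          members = list(m(w[2]), m(w[1]))),
    "3-level GPCN" = list(kind = "gpcn", levels = 3,
                          members = list(m(w[3]), m(w[2]), m(w[1]))),
    "2-level A-GPCN" = list(kind = "agpcn", levels = 2,
                            members = list(m(w[2]), m(w[1]))),
    "3-level A-GPCN" = list(kind = "agpcn", levels = 3,
                            members = list(m(w[3]), m(w[2]), m(w[1]))),
    "N-GCN (1,2,4)" = list(kind = "ngcn", radii = c(1, 2, 4),
                           members = list(m(w[1]), m(w[1]), m(w[1]))),
    "N-GCN (1,2,4,8,16)" = list(kind = "ngcn", radii = c(1, 2, 4, 8, 16),
                                members = rep(list(m(w[1])), 5)),
    "DiffPool" = list(kind = "diffpool", levels = 3,
                      members = list(m(w[3]), m(w[2]), m(w[1]))),
    stop("unknown preset: ", name)
  )
}
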