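#' Closed-form gradient of total predicted energy through a member's first layer
#'
#' For a member whose first graph-convolution pre-activation is
#' `A1 = Z X W1 + b1`, the gradient of the scalar total energy
#' `E = sum(Y)` with respect to the input is
#' `dE/dX = t(Z) %*% (dE/dA1) %*% t(W1)`.  The upstream factor `dE/dA1` is
#' obtained by reverse traversal of the member's remaining layers
#' ([member_upstream_gradient()]).
#'
#' @param Z Structure matrix of the member's level.
#' @param W1 First-layer filter matrix.
#' @param upstream Gradient of `E` with respect to the first-layer
#'   pre-activation (`n x F1`).
#' @return Gradient matrix with the input's shape (`n x F0`).
#' @export
member_input_gradient <- function(Z, W1, upstream) {
  if (nrow(upstream) != nrow(Z) || ncol(upstream) != ncol(W1))
    stop("upstream gradient must match the first-layer pre-activation shape")
  as.matrix(Matrix::crossprod(Z, upstream)) %*% t(W1)
}

#' Upstream gradient dE/dA1 of a member by reverse traversal
#'
#' Runs the member forward caching pre-activations, then backpropagates the
#' gradient of `E = sum(output)` down to the first GCN pre-activation.
#' Accounts for the node-wise concatenation of every GCN layer's output
#' feeding the dense head.
#'
#' @param Z Structure matrix.
#' @param X Input features at this member's level.
#' @param params Member parameters (`gcn`, `dense` lists).
#' @param out_grad Gradient of `E` with respect to the member's output
#'   (`n x 1`).  Defaults to all ones (`E` = sum of this member's own
#'   output); for a prolonged coarse member whose energy is summed at the
#'   fine scale it is the column-sum vector `t(P) %*% 1`.
#' @return `n x F1` gradient at the first pre-activation.
#' @export
member_upstream_gradient <- function(Z, X, params, out_grad = NULL) {
  ng <- length(params$gcn)
  A <- vector("list", ng); H <- vector("list", ng)
  cur <- X
  for (l in seq_len(ng)) {
    A[[l]] <- sweep(as.matrix(Z %*% cur %*% params$gcn[[l]]$W), 2,
                    params$gcn[[l]]$b, "+")
    cur <- pmax(A[[l]], 0)
    H[[l]] <- cur
  }
  C <- do.call(cbind, H)
  nd <- length(params$dense)
  D <- vector("list", nd)
  cur <- C
  for (l in seq_len(nd)) {
    pre <- sweep(cur %*% params$dense[[l]]$W, 2, params$dense[[l]]$b, "+")
    cur <- if (l < nd) 1 / (1 + exp(-pre)) else pre
    D[[l]] <- cur
  }
  # reverse through the dense head
  g <- if (is.null(out_grad)) matrix(1, nrow(X), 1) else out_grad
  for (l in rev(seq_len(nd))) {
    if (l < nd) g <- g * D[[l]] * (1 - D[[l]])
    gin <- g %*% t(params$dense[[l]]$W)
    g <- gin
  }
  # split the concat gradient across GCN layer outputs and walk back
  widths <- vapply(H, ncol, 1L)
  ends <- cumsum(widths); starts <- c(1L, utils::head(ends, -1) + 1L)
  gH <- lapply(seq_len(ng), function(l) g[, starts[l]:ends[l], drop = FALSE])
  gacc <- matrix(0, nrow(X), widths[ng])
  for (l in rev(seq_len(ng))) {
    gacc <- gacc + gH[[l]]
    gA <- gacc * (A[[l]] > 0)
    if (l == 1) return(gA)
    gacc <- as.matrix(Matrix::crossprod(Z, gA)) %*% t(params$gcn[[l]]$W)
  }
}

#' Gradient of the ensemble's total predicted energy w.r.t. the fine input
#'
#' Applies the closed-form first-layer rule to each member and maps coarse
#' gradients back to the fine scale:
#' `dE/dX = sum_i P[1,i] %*% dE_i/dX_i` (fine member: identity map).  The
#' total gradient equals the sum of the per-member contributions exactly.
#'
#' @param model A `gcn_model` (multiscale or flat ensemble kinds).
#' @param X Fine-scale input matrix.
#' @return An `input_gradient`: `dE_dX` plus per-member `contributions`.
#' @export
ensemble_input_gradient <- function(model, X) {
  nmem <- length(model$members)
  P1 <- if (model$kind %in% c("gpcn", "agpcn"))
    composed_projections(model$pairwise_P, model$sizes)
  else vector("list", nmem)
  contribs <- vector("list", nmem)
  for (i in seq_len(nmem)) {
    Xi <- if (is.null(P1[[i]])) X else crossprod(P1[[i]], X)
    # E_i is summed at the fine scale, so the output-layer seed for a
    # prolonged member is the column-sum vector of its prolongation
    og <- if (is.null(P1[[i]])) NULL
          else matrix(Matrix::colSums(P1[[i]]), ncol = 1)
    up <- member_upstream_gradient(model$Z[[i]], Xi, model$members[[i]], og)
    gi <- member_input_gradient(model$Z[[i]], model$members[[i]]$gcn[[1]]$W, up)
    contribs[[i]] <- if (is.null(P1[[i]])) gi else as.matrix(P1[[i]] %*% gi)
  }
  structure(list(dE_dX = Reduce(`+`, contribs), contributions = contribs),
            class = "input_gradient")
}

#' Relax a configuration by gradient descent on predicted energy
#'
#' Descends the model's total predicted energy with respect to the position
#' columns of the input only (velocity and coefficient columns stay frozen,
#' since relaxing them is physically meaningless).  Inputs and predictions
#' live in the model's (normalized) feature space.
#'
#' @param model A `gcn_model`.
#' @param X0 Starting fine-scale input matrix.
#' @param step_size Descent step.
#' @param iters Iterations.
#' @param position_cols Columns of `X` treated as positions (default 1:3).
#' @return List `X` (final), `trajectory` (list of iterates), `energy`
#'   (predicted total per iterate), `diverged` flag.
#' @export
relax_configuration <- function(model, X0, step_size = 1e-3, iters = 50,
                                position_cols = 1:3) {
  X <- X0
  energy <- numeric(iters + 1)
  energy[1] <- sum(model_forward(model, X))
  traj <- list(X)
  diverged <- FALSE
  for (it in seq_len(iters)) {
    g <- ensemble_input_gradient(model, X)$dE_dX
    X[, position_cols] <- X[, position_cols] -
      step_size * g[, position_cols, drop = FALSE]
    e <- sum(model_forward(model, X))
    if (!is.finite(e) || abs(e) > 1e12) {
      diverged <- TRUE
      energy <- energy[seq_len(it)]
      break
    }
    energy[it + 1] <- e
    traj[[it + 1]] <- X
  }
  list(X = traj[[length(traj)]], trajectory = traj, energy = energy,
       diverged = diverged)
}
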