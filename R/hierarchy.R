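#' Assemble a multiscale graph hierarchy
#'
#' Given graphs ordered fine to coarse with strictly decreasing node counts,
#' computes each adjacent pair's optimal prolongation map (at `alpha = 1`)
#' and the composed fine-to-level maps
#' `P[1,i] = P[1,2] %*% ... %*% P[i-1,i]`.
#'
#' @param graphs List of `lattice_graph`s (or Laplacian matrices), fine first.
#' @param maxit,tol Refinement controls passed to [optimize_prolongation()].
#' @return A `gpcn_hierarchy`: `graphs`, `laplacians`, `pairwise`
#'   (prolongation maps between adjacent levels), `composed` (list indexed by
#'   level, `composed[[i]]` maps level-i signals to the fine level; level 1 is
#'   the identity).
#' @export
build_hierarchy <- function(graphs, maxit = 1000, tol = 1e-6) {
  stopifnot(length(graphs) >= 1)
  laps <- lapply(graphs, function(g)
    if (inherits(g, "lattice_graph")) laplacian(g) else g)
  sizes <- vapply(laps, nrow, 1L)
  if (any(diff(sizes) >= 0))
    stop("hierarchy requires strictly decreasing node counts, got: ",
         paste(sizes, collapse = ", "))
  k <- length(laps)
  pairwise <- vector("list", max(0, k - 1))
  composed <- vector("list", k)
  composed[[1]] <- Matrix::Diagonal(sizes[1])
  acc <- NULL
  for (i in seq_len(k - 1)) {
    pairwise[[i]] <- optimize_prolongation(laps[[i + 1]], laps[[i]],
                                           alpha = 1, maxit = maxit, tol = tol)
    acc <- if (is.null(acc)) pairwise[[i]]$P else acc %*% pairwise[[i]]$P
    composed[[i + 1]] <- acc
  }
  structure(list(graphs = graphs, laplacians = laps, sizes = sizes,
                 pairwise = pairwise, composed = composed),
            class = "gpcn_hierarchy")
}

#' @export
print.gpcn_hierarchy <- function(x, ...) {
  cat("graph hierarchy:", paste(x$sizes, collapse = " -> "), "nodes\n")
  for (i in seq_along(x$pairwise))
    cat(sprintf("  P[%d,%d]: objective %.5g\n", i, i + 1,
                x$pairwise[[i]]$objective))
  invisible(x)
}

#' The default microtubule hierarchy
#'
#' Three levels: the fine microtubule `GTube(48,13,3)` (624 nodes); the
#' dimer-level tube `GTube(24,13,1)` (312 nodes), i.e. each alpha-beta
#' monomer pair combined into one unit; and the coarse tube `GTube(24,3,0)`
#' (72 nodes), the winner of the coarsening search.  The `"desk"` scale uses
#' the same family at a quarter length (156/78/18 nodes) for laptop-sized
#' experiments.
#'
#' @param scale `"paper"` (624/312/72) or `"desk"` (156/78/18).
#' @param maxit Refinement iterations for the prolongation maps.
#' @param levels Number of levels to keep (2 drops the coarsest).
#' @return A `gpcn_hierarchy`.
#' @export
microtubule_hierarchy <- function(scale = c("desk", "paper"), maxit = 200,
                                  levels = 3) {
  scale <- match.arg(scale)
  specs <- if (scale == "paper")
    list(tube_spec(48, 13, 3), tube_spec(24, 13, 1), tube_spec(24, 3, 0))
  else
    list(tube_spec(12, 13, 3), tube_spec(6, 13, 1), tube_spec(6, 3, 0))
  specs <- specs[seq_len(levels)]
  build_hierarchy(lapply(specs, build_tube_graph), maxit = maxit)
}

#' Search the offset-tube family for the nearest coarsening
#'
#' Computes the LGDD (at `alpha = 1`) between a fine graph and every
#' candidate `GTube(length, k, p)` for `k` in `k_range`, `p` in `p_range`,
#' with seam edges at each weight in `seam_weights`.  Both the spectral
#' assignment bound (`rlap_value`) and the refined objective
#' (`refined_value`) are reported; candidates are ranked by the refined
#' value.  A failed optimization is recorded as `NA`, not fatal.
#'
#' @param g_fine Fine `lattice_graph` (or Laplacian).
#' @param length Ring count of the candidate tubes.
#' @param k_range,p_range Integer vectors of turn sizes and offsets.
#' @param seam_weights Seam edge weights to score (default 1 and 2; the
#'   doubled variant reflects pairs of seam edges condensed into one).
#' @param maxit Stiefel refinement iterations per candidate.
#' @return A data.frame `(k, p, seam_weight, n_nodes, rlap_value,
#'   refined_value)` sorted by `refined_value`, with the argmin row as
#'   attribute `"best"`.
#' @export
coarsening_search <- function(g_fine, length = 24, k_range = 3:12,
                              p_range = 0:3, seam_weights = c(1, 2),
                              maxit = 50) {
  L_fine <- if (inherits(g_fine, "lattice_graph")) laplacian(g_fine) else g_fine
  sp_fine <- spectral_pair(L_fine)
  grid <- expand.grid(k = k_range, p = p_range, seam_weight = seam_weights)
  # fixed evaluation order: by k, then p, then seam weight (as constructed)
  res <- lapply(seq_len(nrow(grid)), function(r) {
    k <- grid$k[r]; p <- grid$p[r]; w <- grid$seam_weight[r]
    out <- data.frame(k = k, p = p, seam_weight = w, n_nodes = NA_integer_,
                      rlap_value = NA_real_, refined_value = NA_real_)
    tryCatch({
      spec <- tube_spec(length, k, p, seam_weight = w)
      if (spec$n_rings * spec$k_per_turn > nrow(L_fine))
        return(out)                                   # larger than the target
      Lc <- laplacian(build_tube_graph(spec))
      sp_c <- spectral_pair(Lc)
      sa <- spectral_assignment(sp_c, sp_fine, alpha = 1)
      P0 <- as.matrix(sp_fine$vectors %*% (sa$P_tilde %*% t(sp_c$vectors)))
      f0 <- lgdd_objective(P0, Lc, L_fine, 1)
      fr <- if (maxit > 0)
        sqrt(max(0, stiefel_cg(P0, Lc, L_fine, 1, maxit = maxit)$value))
      else f0
      out$n_nodes <- nrow(Lc); out$rlap_value <- f0; out$refined_value <- fr
      out
    }, error = function(e) {
      warning("candidate (k=", k, ", p=", p, ", w=", w, ") failed: ",
              conditionMessage(e))
      out
    })
  })
  res <- do.call(rbind, res)
  res <- res[order(res$refined_value), ]
  rownames(res) <- NULL
  attr(res, "best") <- res[which.min(res$refined_value), ]
  res
}

#' Write coarsening-search results to CSV
#' @param results Data frame from [coarsening_search()].
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_search_results <- function(results, file) {
  utils::write.csv(results, file, row.names = FALSE)
  invisible(file)
}

#' Write a hierarchy to a directory of Matrix Market files plus manifest
#'
#' Stores each level's Laplacian (`L1.mtx`, ...), each pairwise prolongation
#' (`P12.mtx` + JSON sidecar, ...) and a `manifest.json` with sizes and
#' objectives.
#'
#' @param h A `gpcn_hierarchy`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_hierarchy <- function(h, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(h$laplacians))
    write_structure_matrix(h$laplacians[[i]], file.path(dir, sprintf("L%d.mtx", i)))
  for (i in seq_along(h$pairwise))
    write_prolongation(h$pairwise[[i]], file.path(dir, sprintf("P%d%d", i, i + 1)))
  jsonlite::write_json(
    list(sizes = h$sizes,
         objectives = vapply(h$pairwise, function(m) m$objective, 1)),
    file.path(dir, "manifest.json"), auto_unbox = FALSE, digits = NA)
  invisible(dir)
}
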