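#' Offset-tube graph specification
#'
#' An offset tube `GTube(n, k, p)` is the graph of a helical lattice with `n`
#' rings of `k` monomers each, where the lateral closure of each turn is
#' shifted axially by `p` monomer units, creating a seam.  The 13-protofilament
#' microtubule used throughout this package is `GTube(48, 13, 3)`.
#'
#' @param n_rings Number of rings (tube length in monomer units).
#' @param k_per_turn Monomers per turn (protofilament count); at least 3.
#' @param offset Seam pitch `p` in monomer units; must be smaller than
#'   `n_rings`.
#' @param seam_weight Edge weight placed on seam edges (lattice edges have
#'   weight 1).
#' @return An object of class `tube_spec`.
#' @examples
#' tube_spec(48, 13, 3)
#' @export
tube_spec <- function(n_rings, k_per_turn, offset = 0, seam_weight = 1) {
  stopifnot(length(n_rings) == 1, length(k_per_turn) == 1, length(offset) == 1)
  n_rings <- as.integer(n_rings)
  k_per_turn <- as.integer(k_per_turn)
  offset <- as.integer(offset)
  if (is.na(n_rings) || n_rings < 1) stop("n_rings must be a positive integer")
  if (is.na(k_per_turn) || k_per_turn < 3) stop("k_per_turn must be >= 3")
  if (is.na(offset) || offset < 0) stop("offset must be a non-negative integer")
  if (offset >= n_rings)
    stop("invalid tube spec: offset (", offset, ") must be < n_rings (",
         n_rings, ")")
  if (!is.numeric(seam_weight) || seam_weight <= 0)
    stop("seam_weight must be a positive real")
  structure(list(n_rings = n_rings, k_per_turn = k_per_turn, offset = offset,
                 seam_weight = as.numeric(seam_weight)),
            class = "tube_spec")
}

#' @export
print.tube_spec <- function(x, ...) {
  cat(sprintf("GTube(%d, %d, %d)", x$n_rings, x$k_per_turn, x$offset))
  if (x$seam_weight != 1) cat(sprintf(" [seam weight %g]", x$seam_weight))
  cat(sprintf(": %d nodes\n", x$n_rings * x$k_per_turn))
  invisible(x)
}

#' Node id of lattice position (r, j)
#'
#' Maps ring index r (0-based) and position-in-ring j (0-based) to the
#' 1-based node id `r*k + j + 1`.  With this map the labels "nodes 1-26"
#' denote the first two rings of a 13-per-turn tube.
#'
#' @param r Ring index, 0-based.
#' @param j Position in ring, 0-based.
#' @param k Monomers per turn.
#' @return Integer node id (1-based).
#' @export
tube_node_id <- function(r, j, k) as.integer(r * k + j + 1L)

new_lattice_graph <- function(n_nodes, edges, spec = NULL) {
  edges <- as.matrix(edges)
  colnames(edges) <- c("i", "j", "weight")
  # canonical order i < j, sorted
  flip <- edges[, 1] > edges[, 2]
  if (any(flip)) edges[flip, 1:2] <- edges[flip, 2:1]
  if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
  key <- (edges[, 1] - 1) * n_nodes + edges[, 2]
  if (anyDuplicated(key)) stop("duplicate edges in graph construction")
  edges <- edges[order(key), , drop = FALSE]
  structure(list(n_nodes = as.integer(n_nodes), edges = edges, spec = spec),
            class = "lattice_graph")
}

#' @export
print.lattice_graph <- function(x, ...) {
  cat(sprintf("lattice graph: %d nodes, %d edges\n", x$n_nodes, nrow(x$edges)))
  invisible(x)
}

#' Build an offset-tube graph
#'
#' Nodes live at lattice positions `(r, j)` for rings `0..n-1` and in-ring
#' positions `0..k-1`, with id `r*k + j + 1`.  Edges: longitudinal
#' `(r,j)-(r+1,j)` (weight 1), lateral
#' `(r,j)-(r,j+1)` for `j < k-1` (weight 1), and seam edges
#' `(r,k-1)-(r+p,0)` whenever `r+p <= n-1` (weight `seam_weight`).  The seam
#' wiring reproduces a helical lattice of pitch `p` with `n*k` nodes.
#'
#' @param spec A [tube_spec()].
#' @return A `lattice_graph` (node count, weighted edge matrix).
#' @examples
#' g <- build_tube_graph(tube_spec(48, 13, 3))
#' g$n_nodes  # 624
#' @export
build_tube_graph <- function(spec) {
  if (!inherits(spec, "tube_spec")) stop("spec must be a tube_spec")
  n <- spec$n_rings; k <- spec$k_per_turn; p <- spec$offset
  id <- function(r, j) r * k + j + 1L

  e <- vector("list", 3)
  if (n > 1) {
    r <- rep(0:(n - 2), each = k); j <- rep(0:(k - 1), n - 1)
    e[[1]] <- cbind(id(r, j), id(r + 1, j), 1)
  }
  r <- rep(0:(n - 1), each = k - 1); j <- rep(0:(k - 2), n)
  e[[2]] <- cbind(id(r, j), id(r, j + 1), 1)
  rs <- 0:(n - 1); rs <- rs[rs + p <= n - 1]
  if (length(rs))
    e[[3]] <- cbind(id(rs, k - 1), id(rs + p, 0), spec$seam_weight)
  new_lattice_graph(n * k, do.call(rbind, e[!vapply(e, is.null, TRUE)]), spec)
}

#' Build a rectangular grid graph
#'
#' 4-neighbour lattice of `rows x cols` nodes with unit weights and no
#' wraparound.  Node `(r, c)` (0-based) has id `r*cols + c + 1`.
#'
#' @param rows,cols Positive grid dimensions.
#' @return A `lattice_graph`.
#' @export
build_grid_graph <- function(rows, cols) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (is.na(rows) || is.na(cols) || rows < 1 || cols < 1)
    stop("grid dimensions must be positive integers")
  id <- function(r, c) r * cols + c + 1L
  e <- vector("list", 2)
  if (rows > 1) {
    r <- rep(0:(rows - 2), each = cols); c <- rep(0:(cols - 1), rows - 1)
    e[[1]] <- cbind(id(r, c), id(r + 1, c), 1)
  }
  if (cols > 1) {
    r <- rep(0:(rows - 1), each = cols - 1); c <- rep(0:(cols - 2), rows)
    e[[2]] <- cbind(id(r, c), id(r, c + 1), 1)
  }
  e <- e[!vapply(e, is.null, TRUE)]
  if (!length(e)) stop("1x1 grid has no edges")
  new_lattice_graph(rows * cols, do.call(rbind, e))
}

#' Graph Laplacian in the A - D convention
#'
#' Returns `L(G) = A(G) - diag(A(G) %*% 1)`: adjacency off-diagonal, minus
#' weighted degree on the diagonal.  Rows sum to zero and the spectrum is
#' non-positive.  This sign convention (the negative of the more common
#' `D - A`) is used consistently by every spectral routine in the package;
#' the diffusion distance is invariant to flipping the sign of both operands.
#'
#' @param g A `lattice_graph`, or a symmetric adjacency matrix.
#' @return A sparse symmetric `Matrix` of size `n x n`.
#' @examples
#' L <- laplacian(build_tube_graph(tube_spec(4, 3, 0)))
#' range(Matrix::rowSums(L))  # zero row sums
#' @export
laplacian <- function(g) {
  A <- adjacency(g)
  L <- A - Matrix::Diagonal(x = Matrix::rowSums(A))
  methods::as(Matrix::forceSymmetric(L), "generalMatrix")
}

#' Adjacency matrix of a lattice graph
#' @param g A `lattice_graph` or symmetric adjacency matrix.
#' @return Sparse symmetric adjacency `Matrix`.
#' @export
adjacency <- function(g) {
  if (inherits(g, "lattice_graph")) {
    Matrix::sparseMatrix(i = g$edges[, 1], j = g$edges[, 2],
                         x = g$edges[, 3], dims = c(g$n_nodes, g$n_nodes),
                         symmetric = TRUE)
  } else if (is.matrix(g) || inherits(g, "Matrix")) {
    if (nrow(g) != ncol(g)) stop("adjacency must be square")
    methods::as(Matrix::Matrix(g, sparse = TRUE), "CsparseMatrix")
  } else stop("cannot interpret object as a graph")
}

#' Number of structurally nonzero entries of a matrix
#' @param M Dense or sparse matrix.
#' @return Integer count of nonzero entries.
#' @export
nnz <- function(M) {
  if (inherits(M, "sparseMatrix")) Matrix::nnzero(M) else sum(M != 0)
}
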