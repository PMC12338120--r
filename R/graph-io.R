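#' Read and write graphs as 0-based edge-list TSV
#'
#' Columns `i`, `j`, `weight` with 0-based node ids (internally the package
#' uses 1-based ids; the on-disk convention is 0-based).
#'
#' @param g A `lattice_graph`.
#' @param file Path to a TSV file.
#' @param n_nodes Node count on read (defaults to `max(id) + 1`).
#' @return `write_edge_list` returns `file` invisibly; `read_edge_list`
#'   returns a `lattice_graph`.
#' @export
write_edge_list <- function(g, file) {
  df <- data.frame(i = g$edges[, 1] - 1L, j = g$edges[, 2] - 1L,
                   weight = g$edges[, 3])
  utils::write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(file, n_nodes = NULL) {
  df <- utils::read.table(file, header = TRUE, sep = "\t")
  if (is.null(n_nodes)) n_nodes <- max(df$i, df$j) + 1L
  new_lattice_graph(n_nodes, cbind(df$i + 1L, df$j + 1L, df$weight))
}

#' Write / read a structure matrix in Matrix Market coordinate format
#' @param M Matrix (dense or sparse).
#' @param file Path to a `.mtx` file.
#' @return `write_structure_matrix` returns `file` invisibly;
#'   `read_structure_matrix` returns a sparse `Matrix`.
#' @export
write_structure_matrix <- function(M, file) {
  Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(M, sparse = TRUE),
                                          "generalMatrix"), "TsparseMatrix"),
                  file)
  invisible(file)
}

#' @rdname write_structure_matrix
#' @export
read_structure_matrix <- function(file) {
  methods::as(Matrix::readMM(file), "CsparseMatrix")
}

#' Serialize a prolongation map (Matrix Market + JSON sidecar)
#'
#' Writes `<prefix>.mtx` (the matrix) and `<prefix>.json` (alpha, objective,
#' constraint tag and optimization provenance).
#'
#' @param map A `prolongation_map` from [optimize_prolongation()].
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_prolongation <- function(map, prefix) {
  mtx <- paste0(prefix, ".mtx"); js <- paste0(prefix, ".json")
  write_structure_matrix(map$P, mtx)
  jsonlite::write_json(list(alpha = map$alpha, objective = map$objective,
                            constraint = map$constraint,
                            provenance = map$provenance),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(mtx, js))
}

#' @rdname write_prolongation
#' @export
read_prolongation <- function(prefix) {
  P <- as.matrix(read_structure_matrix(paste0(prefix, ".mtx")))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  structure(list(P = P, alpha = meta$alpha, objective = meta$objective,
                 constraint = meta$constraint, provenance = meta$provenance),
            class = "prolongation_map")
}
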