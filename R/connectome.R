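#' Connectome container
#'
#' A connectome is a cell table plus a sparse matrix `W` of synapse counts,
#' with `W[a, b]` the number of synapses from cell `a` onto cell `b`.
#' Counts are non-negative integers; no count threshold is applied at the
#' cell level.  Autapses, if present in the input, are retained.
#'
#' @param cells data.frame with columns `id`, `type` and optionally
#'   `neurotransmitter`.  Cell ids are opaque strings and must be unique.
#' @param edges data.frame with columns `pre`, `post`, `count`; duplicate
#'   (pre, post) rows are summed.
#' @return an object of class `connectome`: a list with elements `cells`
#'   (the cell table, ordered by id within type) and `W` (a
#'   `Matrix::dgCMatrix` with cell ids as dimnames).
#' @export
connectome <- function(cells, edges) {
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  if (!all(c("id", "type") %in% names(cells)))
    stop("cell table must have columns 'id' and 'type'", call. = FALSE)
  cells$id <- as.character(cells$id)
  cells$type <- as.character(cells$type)
  if (is.null(cells$neurotransmitter)) cells$neurotransmitter <- NA_character_
  if (anyDuplicated(cells$id))
    stop("duplicate cell ids in cell table", call. = FALSE)
  # deterministic ordering: by type, then id
  cells <- cells[order(cells$type, cells$id), c("id", "type", "neurotransmitter")]
  rownames(cells) <- NULL

  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("pre", "post", "count") %in% names(edges)))
    stop("edge list must have columns 'pre', 'post', 'count'", call. = FALSE)
  cnt <- edges$count
  if (length(cnt) > 0) {
    if (any(!is.finite(cnt)) || any(cnt < 0) || any(cnt != round(cnt)))
      stop("synapse counts must be non-negative integers", call. = FALSE)
  }
  i <- match(as.character(edges$pre), cells$id)
  j <- match(as.character(edges$post), cells$id)
  if (anyNA(i) || anyNA(j)) {
    bad <- unique(c(edges$pre[is.na(i)], edges$post[is.na(j)]))
    stop("edge list references unknown cell id(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  n <- nrow(cells)
  W <- Matrix::sparseMatrix(i = i, j = j, x = as.numeric(cnt),
                            dims = c(n, n),
                            dimnames = list(cells$id, cells$id))
  W <- methods::as(W, "CsparseMatrix") # duplicates summed by sparseMatrix
  structure(list(cells = cells, W = W), class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat("<connectome> ", nrow(x$cells), " cells, ",
      length(unique(x$cells$type)), " types, ",
      sum(x$W), " synapses\n", sep = "")
  invisible(x)
}

#' Cell ids of a given type
#'
#' @param conn a [connectome].
#' @param type a type label.
#' @return character vector of cell ids, sorted.
#' @export
cells_of_type <- function(conn, type) {
  conn$cells$id[conn$cells$type == type]
}

#' Read a connectome from CSV files
#'
#' The cell table has columns `id,type` (and optionally `neurotransmitter`);
#' the edge list has columns `pre,post,count`.  Both are UTF-8 CSV with a
#' header row.  Duplicate (pre, post) rows are summed.
#'
#' @param cell_table_path,edge_list_path paths to the CSV files.
#' @return a [connectome].
#' @export
load_connectome <- function(cell_table_path, edge_list_path) {
  cells <- utils::read.csv(cell_table_path, stringsAsFactors = FALSE,
                           colClasses = "character")
  edges <- utils::read.csv(edge_list_path, stringsAsFactors = FALSE)
  if (!all(c("pre", "post", "count") %in% names(edges)))
    stop("edge list must have columns 'pre', 'post', 'count'", call. = FALSE)
  connectome(cells, edges)
}

#' Write a connectome to CSV files
#'
#' Inverse of [load_connectome()]; writing then reading round-trips the
#' synapse-count matrix exactly.
#'
#' @param conn a [connectome].
#' @inheritParams load_connectome
#' @export
write_connectome <- function(conn, cell_table_path, edge_list_path) {
  utils::write.csv(conn$cells, cell_table_path, row.names = FALSE, na = "")
  tw <- Matrix::summary(conn$W)
  edges <- data.frame(pre = rownames(conn$W)[tw$i],
                      post = colnames(conn$W)[tw$j],
                      count = tw$x, stringsAsFactors = FALSE)
  edges <- edges[order(edges$pre, edges$post), , drop = FALSE]
  utils::write.csv(edges, edge_list_path, row.names = FALSE)
  invisible(conn)
}

#' Type-to-type synapse count matrix
#'
#' Aggregates the cell-level counts into `W_AB`, the total number of synapses
#' from cell type A onto cell type B: `W_AB = sum_{a in A} sum_{b in B} W_ab`.
#' The grand total over all type pairs equals the grand total over all cell
#' pairs exactly.
#'
#' @param conn a [connectome].
#' @return a dense base matrix with type labels as dimnames.
#' @export
type_matrix <- function(conn) {
  types <- sort(unique(conn$cells$type))
  f <- factor(conn$cells$type[match(rownames(conn$W), conn$cells$id)],
              levels = types)
  tw <- Matrix::summary(conn$W)
  M <- matrix(0, length(types), length(types), dimnames = list(types, types))
  if (nrow(tw) > 0) {
    ti <- as.integer(f[tw$i])
    tj <- as.integer(f[tw$j])
    agg <- tapply(tw$x, list(ti, tj), sum)
    nz <- which(!is.na(agg), arr.ind = TRUE)
    M[cbind(as.integer(rownames(agg))[nz[, 1]],
            as.integer(colnames(agg))[nz[, 2]])] <- agg[nz]
  }
  M
}

#' Presumed synaptic sign table
#'
#' Maps type labels to presumed signs used when drawing wiring diagrams.
#' Signs are annotations supplied by the user (e.g. from neurotransmitter
#' predictions: cholinergic types presumed excitatory, GABAergic or
#' glutamatergic types presumed inhibitory); they are not computed here.
#'
#' @param types character vector of type labels.
#' @param signs character vector, one of `"excitatory"`, `"inhibitory"`,
#'   `"unknown"` per type.
#' @return named character vector (class `type_sign_table`).
#' @export
type_sign_table <- function(types = character(0), signs = character(0)) {
  stopifnot(length(types) == length(signs))
  if (length(signs) > 0 &&
      !all(signs %in% c("excitatory", "inhibitory", "unknown")))
    stop("signs must be excitatory, inhibitory or unknown", call. = FALSE)
  structure(stats::setNames(as.character(signs), types),
            class = "type_sign_table")
}

#' Default hexel-type roster
#'
#' Hexel types are the modular cell types (one cell per column) with
#' approximately one-ommatidium-wide receptive fields; they serve as the
#' retinotopic sources of all connectivity maps.  The default roster is
#' Tm1, Tm2, Tm9, Mi1, Mi4, Mi9 and L1–L5; it is configuration, not a fact
#' computed from data.
#'
#' @return character vector of type labels.
#' @export
hexel_roster <- function() {
  c("Tm1", "Tm2", "Tm9", "Mi1", "Mi4", "Mi9", "L1", "L2", "L3", "L4", "L5")
}
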