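#' Maximum-weight rectangular linear assignment
#'
#' Solves the linear sum assignment problem by the shortest augmenting path
#' method (Jonker–Volgenant style, with dual potentials), the same primitive
#' as the classical Hungarian algorithm.  With `nr <= nc` every row is
#' matched to a distinct column so that the total affinity is maximal; the
#' rectangular case is handled directly (unmatched columns remain free), and
#' `nr > nc` is solved by transposition.
#'
#' No installed package provides a weighted assignment solver, so it is
#' implemented here and validated against exhaustive permutation search.
#'
#' @param affinity numeric matrix of non-negative weights.
#' @return integer vector of length `nrow(affinity)`: for each row, the index
#'   of its matched column (NA only possible when `nr > nc`).
#' @export
max_weight_assignment <- function(affinity) {
  A <- as.matrix(affinity)
  stopifnot(all(is.finite(A)))
  if (nrow(A) > ncol(A)) {
    colsol <- max_weight_assignment(t(A))
    rowsol <- rep(NA_integer_, nrow(A))
    rowsol[colsol] <- seq_along(colsol)
    return(rowsol)
  }
  # max-weight complete matching of rows == min-cost with C = max(A) - A
  C <- max(A) - A
  n <- nrow(C)
  m <- ncol(C)
  u <- numeric(n)
  v <- numeric(m)
  col4row <- rep(NA_integer_, n)
  row4col <- rep(NA_integer_, m)
  for (cur in seq_len(n)) {
    spc <- rep(Inf, m)        # shortest path cost to each column
    path <- rep(NA_integer_, m)
    done <- logical(m)        # columns finalized (in SC)
    in_sr <- rep(FALSE, n)    # rows visited
    minval <- 0
    i <- cur
    sink <- NA_integer_
    while (is.na(sink)) {
      in_sr[i] <- TRUE
      rem <- which(!done)
      r <- minval + C[i, rem] - u[i] - v[rem]
      better <- r < spc[rem]
      spc[rem[better]] <- r[better]
      path[rem[better]] <- i
      j <- rem[which.min(spc[rem])]
      minval <- spc[j]
      done[j] <- TRUE
      if (is.na(row4col[j])) sink <- j else i <- row4col[j]
    }
    # dual update
    u[cur] <- u[cur] + minval
    sr <- which(in_sr & seq_len(n) != cur)
    if (length(sr) > 0) u[sr] <- u[sr] + minval - spc[col4row[sr]]
    sc <- which(done)
    v[sc] <- v[sc] - (minval - spc[sc])
    # augment
    j <- sink
    repeat {
      i <- path[j]
      row4col[j] <- i
      jnew <- col4row[i]
      col4row[i] <- j
      if (i == cur) break
      j <- jnew
    }
  }
  col4row
}

#' Lattice assignment of a cell type
#'
#' A partial, injective map from cells of one type to hexagonal lattice
#' points: at most one cell of the type per column; partial coverage is
#' allowed.
#'
#' @param id character vector of cell ids.
#' @param p,q integer axial coordinates, one per id.
#' @param type the type label the assignment covers.
#' @return data.frame of class `lattice_assignment` with columns `id`, `p`,
#'   `q` and attribute `type`.
#' @export
lattice_assignment <- function(id, p, q, type = NA_character_) {
  stopifnot(length(id) == length(p), length(p) == length(q))
  if (anyDuplicated(id))
    stop("duplicate cell id in lattice assignment", call. = FALSE)
  if (length(p) > 0 && anyDuplicated(cbind(p, q)))
    stop("more than one cell assigned to the same lattice point", call. = FALSE)
  out <- data.frame(id = as.character(id), p = as.integer(p),
                    q = as.integer(q), stringsAsFactors = FALSE)
  out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, type = type, class = c("lattice_assignment", "data.frame"))
}

#' Assign cells of one type to lattice points by weighted matching
#'
#' Matches target-type cells one-to-one with cells of an already-placed
#' reference assignment, maximizing total synaptic affinity (Hungarian /
#' Jonker–Volgenant assignment applied to the connectivity matrix); each
#' matched target cell inherits the lattice point of its reference partner.
#' With unequal cardinalities a rectangular assignment is solved and the
#' excess cells (or reference points) are left out.  Target cells matched at
#' zero affinity are left unassigned.
#'
#' @param conn a [connectome].
#' @param reference a [lattice_assignment] of the reference type's cells.
#' @param target_type type label of the cells to place.
#' @param direction which synapses define affinity between a target cell `t`
#'   and reference cell `r`: `"both"` (default) `W[t,r] + W[r,t]`,
#'   `"to_ref"` `W[t,r]`, `"from_ref"` `W[r,t]`.
#' @return a [lattice_assignment] for `target_type`.
#' @export
assign_by_matching <- function(conn, reference, target_type,
                               direction = c("both", "to_ref", "from_ref")) {
  direction <- match.arg(direction)
  tgt <- cells_of_type(conn, target_type)
  if (length(tgt) == 0) stop("no cells of type ", target_type, call. = FALSE)
  ref_ids <- reference$id
  if (length(ref_ids) == 0) stop("reference assignment is empty", call. = FALSE)
  Wtr <- as.matrix(conn$W[tgt, ref_ids, drop = FALSE])
  Wrt <- as.matrix(conn$W[ref_ids, tgt, drop = FALSE])
  A <- switch(direction,
              both = Wtr + t(Wrt),
              to_ref = Wtr,
              from_ref = t(Wrt))
  if (all(A == 0)) {
    warning("all-zero affinity between ", target_type,
            " and reference; empty assignment", call. = FALSE)
    return(lattice_assignment(character(0), integer(0), integer(0),
                              type = target_type))
  }
  sol <- max_weight_assignment(A)
  rows <- which(!is.na(sol))
  w <- A[cbind(rows, sol[rows])]
  keep <- rows[w > 0]
  n_skip <- length(tgt) - length(keep)
  if (n_skip > 0)
    message(target_type, ": ", n_skip, " cell(s) left unassigned")
  ref_match <- sol[keep]
  pos <- match(ref_ids[ref_match], reference$id)
  lattice_assignment(tgt[keep], reference$p[pos], reference$q[pos],
                     type = target_type)
}

#' Assign several types in sequence
#'
#' Applies [assign_by_matching()] along a chain, mirroring the study design
#' in which L cells are placed in one-to-one correspondence with anchored
#' Mi1 cells and the remaining hexel types with L cells.  Each chain element
#' is `c(target_type, reference_type)`; every reference must be the anchor
#' type or a target assigned earlier in the chain.
#'
#' @param conn a [connectome].
#' @param anchor a [lattice_assignment] for the anchor type (input; e.g. from
#'   a lattice-grid file or the synthetic generator).
#' @param chain list of 2-element character vectors `(target, reference)`.
#' @param direction passed to [assign_by_matching()].
#' @return named list of [lattice_assignment]s, anchor included.
#' @export
chain_assign <- function(conn, anchor, chain, direction = "both") {
  anchor_type <- attr(anchor, "type")
  out <- stats::setNames(list(anchor), anchor_type)
  for (step in chain) {
    stopifnot(length(step) == 2)
    tgt <- step[[1]]
    ref <- step[[2]]
    if (!ref %in% names(out))
      stop("chain references type '", ref,
           "' before it has been assigned", call. = FALSE)
    out[[tgt]] <- assign_by_matching(conn, out[[ref]], tgt,
                                     direction = direction)
  }
  out
}

#' Default assignment chain
#'
#' L1–L5 are matched to the anchor type Mi1, then the remaining hexel types
#' to L1.  Which L type mediates the second stage is configuration; L1 is
#' the default.
#'
#' @param roster hexel-type roster (see [hexel_roster()]).
#' @param anchor_type the anchored type.
#' @param l_mediator the L type used to place non-L hexel types.
#' @return list of `c(target, reference)` pairs.
#' @export
default_chain <- function(roster = hexel_roster(), anchor_type = "Mi1",
                          l_mediator = "L1") {
  l_types <- intersect(c("L1", "L2", "L3", "L4", "L5"), roster)
  rest <- setdiff(roster, c(anchor_type, l_types))
  c(lapply(l_types, function(t) c(t, anchor_type)),
    lapply(rest, function(t) c(t, l_mediator)))
}

#' Read / write the lattice-grid CSV dialect
#'
#' In the grid dialect the element in the `p`-th row and `q`-th column
#' contains the id of the cell of a given type at lattice location (p, q),
#' with rows indexed by `p` ascending downward and columns by `q` ascending
#' rightward (0-based); an empty string marks a vacant column.  Only
#' non-negative coordinates can be represented; the tidy `id,p,q` CSV
#' written by [write_assignment_csv()] is the preferred machine format.
#'
#' @param path file path.
#' @param type type label to attach to the assignment.
#' @return `read_lattice_grid()`: a [lattice_assignment].
#' @export
read_lattice_grid <- function(path, type = NA_character_) {
  g <- utils::read.csv(path, header = FALSE, colClasses = "character")
  g <- as.matrix(g)
  nz <- which(g != "", arr.ind = TRUE)
  ids <- g[nz]
  if (anyDuplicated(ids))
    stop("duplicate cell id in lattice grid", call. = FALSE)
  lattice_assignment(ids, nz[, 1] - 1L, nz[, 2] - 1L, type = type)
}

#' @rdname read_lattice_grid
#' @param assignment a [lattice_assignment] with non-negative coordinates.
#' @export
write_lattice_grid <- function(assignment, path) {
  if (nrow(assignment) == 0) stop("empty assignment", call. = FALSE)
  if (any(assignment$p < 0) || any(assignment$q < 0))
    stop("grid dialect requires non-negative coordinates; ",
         "use write_assignment_csv()", call. = FALSE)
  g <- matrix("", max(assignment$p) + 1, max(assignment$q) + 1)
  g[cbind(assignment$p + 1, assignment$q + 1)] <- assignment$id
  utils::write.table(g, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, qmethod = "double")
  invisible(assignment)
}

#' Tidy assignment CSV (id, p, q)
#'
#' @param assignment a [lattice_assignment].
#' @param path file path.
#' @export
write_assignment_csv <- function(assignment, path) {
  utils::write.csv(as.data.frame(assignment), path, row.names = FALSE)
  invisible(assignment)
}

#' @rdname write_assignment_csv
#' @param type type label to attach.
#' @export
read_assignment_csv <- function(path, type = NA_character_) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(id = "character"))
  lattice_assignment(d$id, d$p, d$q, type = type)
}
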