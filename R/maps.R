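#' Hexel map
#'
#' A sparse map from hexagonal lattice coordinates to non-negative values:
#' synapse counts for monosynaptic maps, backward random-walk probabilities
#' for di-/tri-synaptic maps.
#'
#' @param p,q integer axial coordinates.
#' @param value non-negative weights; duplicates at the same coordinate are
#'   summed.
#' @param unit `"synapse_count"` or `"probability"`.
#' @return data.frame of class `hexel_map` with columns `p`, `q`, `value`
#'   and attribute `unit`, sorted by (p, q), zero entries dropped.
#' @export
hexel_map <- function(p = integer(0), q = integer(0), value = numeric(0),
                      unit = c("synapse_count", "probability")) {
  unit <- match.arg(unit)
  stopifnot(length(p) == length(q), length(q) == length(value))
  if (length(value) > 0 && any(value < 0))
    stop("hexel map values must be non-negative", call. = FALSE)
  d <- data.frame(p = as.integer(p), q = as.integer(q), value = value)
  if (nrow(d) > 0) {
    key <- paste(d$p, d$q)
    if (anyDuplicated(key)) {
      agg <- stats::aggregate(value ~ p + q, data = d, FUN = sum)
      d <- agg
    }
    d <- d[d$value != 0, , drop = FALSE]
    d <- d[order(d$p, d$q), , drop = FALSE]
  }
  rownames(d) <- NULL
  structure(d, unit = unit, class = c("hexel_map", "data.frame"))
}

#' Total weight of a hexel map
#' @param m a [hexel_map].
#' @export
map_total <- function(m) sum(m$value)

# value of map at coordinates (vectorized); 0 where absent
map_lookup <- function(m, p, q) {
  idx <- match(paste(p, q), paste(m$p, m$q))
  out <- m$value[idx]
  out[is.na(out)] <- 0
  out
}

#' Write / read a hexel map as CSV (p, q, value)
#' @param m a [hexel_map].
#' @param path file path.
#' @export
write_map_csv <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# unit: ", attr(m, "unit")), con)
  utils::write.csv(as.data.frame(m), con, row.names = FALSE)
  invisible(m)
}

#' @rdname write_map_csv
#' @export
read_map_csv <- function(path) {
  first <- readLines(path, n = 1)
  unit <- sub("^# unit: ", "", first)
  d <- utils::read.csv(path, comment.char = "#")
  hexel_map(d$p, d$q, d$value, unit = unit)
}

#' Monosynaptic connectivity map onto one cell
#'
#' Places, at the lattice position `r_a` of every assigned source cell `a`
#' of type `A`, the number of synapses `W[a, b]` onto the target cell `b`
#' (or the input fraction `P[a, b]` in `input_fraction` mode):
#' `f_Ab(r) = sum_{a in A} delta(r, r_a) W_ab`.
#' Source cells of type A without a lattice assignment are skipped and their
#' count reported as a message.
#'
#' @param conn a [connectome].
#' @param assign a [lattice_assignment] covering type `A`.
#' @param A source (hexel) type label.
#' @param b target cell id.
#' @param weight_mode `"synapse_count"` (default) or `"input_fraction"`.
#' @param P optional precomputed cell-level input-fraction matrix.
#' @return a [hexel_map].
#' @export
mono_map_cell <- function(conn, assign, A, b,
                          weight_mode = c("synapse_count", "input_fraction"),
                          P = NULL) {
  weight_mode <- match.arg(weight_mode)
  if (!b %in% conn$cells$id) stop("unknown cell id '", b, "'", call. = FALSE)
  a_cells <- cells_of_type(conn, A)
  assigned <- intersect(a_cells, assign$id)
  n_skip <- length(a_cells) - length(assigned)
  if (n_skip > 0)
    message(n_skip, " unassigned ", A, " cell(s) skipped")
  if (length(assigned) == 0)
    return(hexel_map(unit = if (weight_mode == "synapse_count")
      "synapse_count" else "probability"))
  M <- if (weight_mode == "synapse_count") conn$W else
    if (is.null(P)) input_fractions(conn$W, quiet = TRUE) else P
  w <- as.numeric(M[assigned, b])
  pos <- match(assigned, assign$id)
  hexel_map(assign$p[pos], assign$q[pos], w,
            unit = if (weight_mode == "synapse_count") "synapse_count"
            else "probability")
}

#' Disynaptic pathway map onto one cell
#'
#' `f_ABc(r) = sum_{a in A} sum_{b in B} delta(r, r_a) P_ab P_bc`:
#' the probability that a backwards random walk from target cell `c` steps
#' to an intermediary of type `B` and then to a source of type `A` located
#' at `r`.  Intermediary cells need no lattice assignment; the map is
#' indexed by source position only.  Summed over all positions and all
#' source and intermediary types, these maps total 1 for any target with
#' input.
#'
#' @param conn a [connectome].
#' @param assign [lattice_assignment] for source type `A`.
#' @param A source type; `B` intermediary type; `target` target cell id.
#' @param B intermediary type label.
#' @param target target cell id.
#' @param P optional precomputed cell-level input-fraction matrix
#'   (`input_fractions(conn$W)`); pass it when building many maps.
#' @return a [hexel_map] in probability units.
#' @export
di_map_cell <- function(conn, assign, A, B, target, P = NULL) {
  if (!target %in% conn$cells$id)
    stop("unknown cell id '", target, "'", call. = FALSE)
  if (is.null(P)) P <- input_fractions(conn$W, quiet = TRUE)
  a_cells <- intersect(cells_of_type(conn, A), assign$id)
  b_cells <- cells_of_type(conn, B)
  if (length(a_cells) == 0 || length(b_cells) == 0)
    return(hexel_map(unit = "probability"))
  w <- as.numeric(P[a_cells, b_cells, drop = FALSE] %*%
                    P[b_cells, target, drop = FALSE])
  pos <- match(a_cells, assign$id)
  hexel_map(assign$p[pos], assign$q[pos], w, unit = "probability")
}

#' Trisynaptic pathway map onto one cell
#'
#' Defined analogously to [di_map_cell()] with weight
#' `P_ab P_bc P_cd` placed at `r_a` for the pathway A -> B -> C -> target d.
#'
#' @inheritParams di_map_cell
#' @param C second intermediary type label.
#' @export
tri_map_cell <- function(conn, assign, A, B, C, target, P = NULL) {
  if (!target %in% conn$cells$id)
    stop("unknown cell id '", target, "'", call. = FALSE)
  if (is.null(P)) P <- input_fractions(conn$W, quiet = TRUE)
  a_cells <- intersect(cells_of_type(conn, A), assign$id)
  b_cells <- cells_of_type(conn, B)
  c_cells <- cells_of_type(conn, C)
  if (length(a_cells) == 0 || length(b_cells) == 0 || length(c_cells) == 0)
    return(hexel_map(unit = "probability"))
  w <- as.numeric(P[a_cells, b_cells, drop = FALSE] %*%
                    P[b_cells, c_cells, drop = FALSE] %*%
                    P[c_cells, target, drop = FALSE])
  pos <- match(a_cells, assign$id)
  hexel_map(assign$p[pos], assign$q[pos], w, unit = "probability")
}

#' Centre of a hexel map
#'
#' Convolves the map with a linear filter equal to 1.1 in the central column
#' and 1 in its six neighbouring columns, and returns the argmax of the
#' result.  Ties are broken toward the smallest `p + q`, then smallest `p`.
#'
#' @param m a non-empty [hexel_map].
#' @return named integer vector `c(p, q)`.
#' @export
centre_of_map <- function(m) {
  if (nrow(m) == 0) stop("cannot take the centre of an empty map", call. = FALSE)
  off <- rbind(c(0, 0), hex_neighbour_offsets())
  # candidates: support plus its neighbourhood
  cand <- unique(do.call(rbind, lapply(seq_len(nrow(off)), function(k)
    cbind(m$p + off[k, 1], m$q + off[k, 2]))))
  val <- 1.1 * map_lookup(m, cand[, 1], cand[, 2])
  for (k in 2:7) {
    val <- val + map_lookup(m, cand[, 1] - off[k, 1], cand[, 2] - off[k, 2])
  }
  best <- which(val == max(val))
  if (length(best) > 1) {
    ord <- order(cand[best, 1] + cand[best, 2], cand[best, 1])
    best <- best[ord[1]]
  }
  stats::setNames(as.integer(cand[best, ]), c("p", "q"))
}

#' Translate a hexel map by a lattice vector
#'
#' @param m a [hexel_map].
#' @param dp,dq integer shift.
#' @export
shift_map <- function(m, dp, dq) {
  hexel_map(m$p + dp, m$q + dq, m$value, unit = attr(m, "unit"))
}

#' Align, crop and average per-cell maps
#'
#' Each map is translated so that its centre sits at the origin, cropped to
#' the hexagonal ball of radius `window_radius`, and averaged hexel-wise
#' over cells; hexels absent from a map count as 0 (maps are dense fields
#' sampled sparsely).  The per-hexel spread across cells is the population
#' standard deviation.  When each centre is the cell's own lattice location,
#' the mean of synapse-count maps equals the type-average map
#' `f_AB(r) = (1/|B|) sum_{a,b} delta(r, r_a - r_b) W_ab` inside the window.
#'
#' @param maps list of [hexel_map]s.
#' @param centres list or matrix of `c(p, q)` centres, one per map.
#' @param window_radius positive integer crop radius (columns).
#' @return list with elements `mean` ([hexel_map]), `sd` ([hexel_map],
#'   zero entries retained as absent), and `n`.
#' @export
align_and_average <- function(maps, centres, window_radius = 8) {
  if (window_radius < 1) stop("window_radius must be >= 1", call. = FALSE)
  n <- length(maps)
  stopifnot(n >= 1)
  if (is.matrix(centres)) centres <- asplit(centres, 1)
  stopifnot(length(centres) == n)
  ball <- hex_ball(window_radius)
  acc <- matrix(0, nrow(ball), n)
  for (k in seq_len(n)) {
    ctr <- centres[[k]]
    acc[, k] <- map_lookup(maps[[k]], ball$p + ctr[1], ball$q + ctr[2])
  }
  mu <- rowMeans(acc)
  sdv <- sqrt(rowMeans(acc^2) - mu^2)
  sdv[sdv < 0 | is.nan(sdv)] <- 0
  unit <- attr(maps[[1]], "unit")
  list(mean = hexel_map(ball$p, ball$q, mu, unit = unit),
       sd = hexel_map(ball$p, ball$q, sdv, unit = unit),
       n = n)
}

#' Centre from a designated reference pathway
#'
#' For targets with strong direct hexel input the reference is the
#' monosynaptic map from a chosen source type; for targets whose direct
#' hexel input is weak or absent (LC-style cells) the reference is their
#' strongest disynaptic pathway map.  Cells whose reference map is empty are
#' excluded from averaging by returning NULL.
#'
#' @param conn a [connectome].
#' @param assign [lattice_assignment] of the reference pathway's source type.
#' @param pathway character vector of type labels ending at the intermediary:
#'   `c(A)` for a monosynaptic reference, `c(A, B)` for a disynaptic one.
#' @param target target cell id.
#' @param P optional precomputed cell-level input fractions.
#' @return `c(p, q)` centre, or NULL if the reference map is empty.
#' @export
reference_centre <- function(conn, assign, pathway, target, P = NULL) {
  m <- if (length(pathway) == 1) {
    mono_map_cell(conn, assign, pathway[1], target)
  } else if (length(pathway) == 2) {
    di_map_cell(conn, assign, pathway[1], pathway[2], target, P = P)
  } else stop("reference pathway must have 1 or 2 types", call. = FALSE)
  if (nrow(m) == 0) {
    message("empty reference map for cell ", target, "; excluded")
    return(NULL)
  }
  centre_of_map(m)
}
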