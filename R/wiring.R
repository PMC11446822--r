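#' Thresholded, signed type-to-type wiring diagram
#'
#' Keeps the directed edge A -> B iff the input fraction `P_AB` is at least
#' `threshold` (inclusive, "at least 3%" being the default convention), and
#' annotates each edge with the presumed sign of its presynaptic type.
#'
#' @param P type-level input-fraction matrix.
#' @param types type labels to include as nodes.
#' @param threshold inclusive input-fraction threshold in `[0, 1]`.
#' @param signs optional [type_sign_table]; types missing from it get sign
#'   `"unknown"`.
#' @return object of class `wiring_diagram`: list with `nodes`, `threshold`
#'   and `edges` (data.frame `pre`, `post`, `fraction`, `sign`, ordered by
#'   pre then post).
#' @export
build_wiring <- function(P, types, threshold = 0.03, signs = NULL) {
  stopifnot(threshold >= 0, threshold <= 1)
  missing_t <- setdiff(types, rownames(P))
  if (length(missing_t) > 0)
    stop("unknown type(s): ", paste(missing_t, collapse = ", "), call. = FALSE)
  sub <- P[types, types, drop = FALSE]
  keep <- which(sub >= threshold & sub > 0, arr.ind = TRUE)
  edges <- data.frame(pre = types[keep[, 1]], post = types[keep[, 2]],
                      fraction = sub[keep], stringsAsFactors = FALSE)
  sgn <- function(t) {
    if (is.null(signs) || is.na(match(t, names(signs)))) "unknown"
    else unname(signs[t])
  }
  edges$sign <- vapply(edges$pre, sgn, character(1))
  edges <- edges[order(edges$pre, edges$post), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = types, threshold = threshold, edges = edges),
            class = "wiring_diagram")
}

#' @export
print.wiring_diagram <- function(x, ...) {
  cat("<wiring_diagram> ", length(x$nodes), " types, ", nrow(x$edges),
      " edges at threshold ", x$threshold, "\n", sep = "")
  invisible(x)
}

#' Strong synaptic partners of a cell
#'
#' Partners connected by strictly more than `min_synapses` synapses
#' (the ">4 synapses" convention of strong-partner visualizations), sorted
#' by count descending then id.
#'
#' @param conn a [connectome].
#' @param cell cell id.
#' @param direction `"pre"` for presynaptic partners (inputs to `cell`),
#'   `"post"` for postsynaptic partners.
#' @param min_synapses strict lower bound on the synapse count.
#' @return data.frame with columns `id`, `type`, `count`.
#' @export
strong_partners <- function(conn, cell, direction = c("pre", "post"),
                            min_synapses = 4) {
  direction <- match.arg(direction)
  stopifnot(min_synapses >= 0)
  if (!cell %in% conn$cells$id)
    stop("unknown cell id '", cell, "'", call. = FALSE)
  w <- if (direction == "pre") conn$W[, cell] else conn$W[cell, ]
  w <- as.numeric(w)
  ids <- rownames(conn$W)
  keep <- which(w > min_synapses)
  d <- data.frame(id = ids[keep],
                  type = conn$cells$type[match(ids[keep], conn$cells$id)],
                  count = w[keep], stringsAsFactors = FALSE)
  d <- d[order(-d$count, d$id), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Export a wiring diagram
#'
#' `write_wiring_csv()` writes the edge list; `write_wiring_dot()` writes a
#' GraphViz DOT graph in which presumed-excitatory edges end in arrowheads
#' and presumed-inhibitory edges end in circles.
#'
#' @param wd a [build_wiring()] result.
#' @param path file path.
#' @export
write_wiring_csv <- function(wd, path) {
  utils::write.csv(wd$edges, path, row.names = FALSE)
  invisible(wd)
}

#' @rdname write_wiring_csv
#' @export
write_wiring_dot <- function(wd, path) {
  head_style <- c(excitatory = "normal", inhibitory = "odot",
                  unknown = "empty")
  lines <- c("digraph wiring {",
             paste0("  // input-fraction threshold ", wd$threshold),
             paste0("  \"", wd$nodes, "\";"),
             sprintf("  \"%s\" -> \"%s\" [arrowhead=%s, label=\"%.3f\"];",
                     wd$edges$pre, wd$edges$post,
                     head_style[wd$edges$sign], wd$edges$fraction),
             "}")
  writeLines(lines, path)
  invisible(wd)
}

#' Precision and recall of recovered wiring edges
#'
#' @param wd a [build_wiring()] result.
#' @param intended data.frame with columns `pre`, `post` of intended edges.
#' @return list with `precision`, `recall`, `n_found`, `n_intended`.
#' @export
wiring_edge_scores <- function(wd, intended) {
  found <- paste(wd$edges$pre, wd$edges$post)
  truth <- paste(intended$pre, intended$post)
  tp <- sum(found %in% truth)
  list(precision = if (length(found) == 0) NA_real_ else tp / length(found),
       recall = if (length(truth) == 0) NA_real_ else tp / length(truth),
       n_found = length(found), n_intended = length(truth))
}
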