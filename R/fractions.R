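#' Input fractions
#'
#' Normalizes a synapse-count matrix so that every column sums to 1:
#' `P[a, b] = W[a, b] / sum_c W[c, b]`, the fraction of input synapses to
#' `b` contributed by `a`.  The same normalization applies to the cell-level
#' matrix `W_ab` and the type-level matrix `W_AB`.  `P` is the transition
#' matrix of the backwards random walk along input synapses: a walker at `b`
#' picks one of `b`'s input synapses uniformly at random and crosses it
#' retrogradely, arriving at `a` with probability `P[a, b]`.
#'
#' Columns with zero input pass through as all-zero (never NaN); their count
#' is reported as a message.
#'
#' @param m non-negative count matrix (base matrix or `Matrix` sparse).
#' @param quiet suppress the zero-column message.
#' @return column-stochastic matrix of the same class and dimnames.
#' @export
input_fractions <- function(m, quiet = FALSE) {
  if (min(m) < 0) stop("counts must be non-negative", call. = FALSE)
  cs <- Matrix::colSums(m)
  nzero <- sum(cs == 0)
  if (nzero > 0 && !quiet)
    message(nzero, " column(s) with zero input left as zero")
  inv <- ifelse(cs > 0, 1 / cs, 0)
  if (inherits(m, "Matrix")) {
    P <- m %*% Matrix::Diagonal(x = inv)
    dimnames(P) <- dimnames(m)
    P
  } else {
    sweep(m, 2, ifelse(cs > 0, cs, 1), "/")
  }
}

#' Anatomical strength of a disynaptic pathway
#'
#' The strength of the pathway A -> B -> C is `P_AB * P_BC`: the probability
#' of walking the pathway backwards (from C to A) along input synapses.
#'
#' @param P type-level column-stochastic input-fraction matrix.
#' @param A,B,C type labels (source, intermediary, target).
#' @return numeric scalar in `[0, 1]`.
#' @export
disynaptic_strength <- function(P, A, B, C) {
  for (t in c(A, B, C)) {
    if (!t %in% rownames(P))
      stop("unknown type '", t, "'", call. = FALSE)
  }
  P[A, B] * P[B, C]
}

#' Rank disynaptic pathways into a target type
#'
#' Enumerates pathways source -> intermediary -> target with the source
#' restricted to the hexel roster and the intermediary constrained to not be
#' a hexel type (optionally also to a presumed sign, e.g. excitatory-only,
#' the convention used for LC10ev-style targets).  Pathways are sorted by
#' anatomical strength `P_AB * P_BC` descending with deterministic
#' tie-breaks (strength desc, intermediary asc, source asc).
#'
#' @param P type-level input-fraction matrix.
#' @param target target type label.
#' @param sources hexel roster: allowed source types.
#' @param intermediaries candidate intermediary types; defaults to all types
#'   of `P` not in `sources`.
#' @param signs optional [type_sign_table] used with `sign_filter`.
#' @param sign_filter if non-NULL, keep only intermediaries of this presumed
#'   sign (e.g. `"excitatory"`).
#' @param k number of pathways to return (default all).
#' @param per_intermediary if TRUE, report for each intermediary only the
#'   single strongest pathway over sources (the one-representative-per-
#'   intermediary reporting convention).
#' @return data.frame with columns `source`, `intermediary`, `target`,
#'   `strength`, sorted.
#' @export
rank_pathways <- function(P, target, sources, intermediaries = NULL,
                          signs = NULL, sign_filter = NULL, k = Inf,
                          per_intermediary = FALSE) {
  stopifnot(k >= 1)
  if (!target %in% colnames(P))
    stop("unknown target type '", target, "'", call. = FALSE)
  all_types <- rownames(P)
  sources <- intersect(sources, all_types)
  if (is.null(intermediaries)) intermediaries <- all_types
  intermediaries <- setdiff(intersect(intermediaries, all_types), sources)
  if (!is.null(sign_filter)) {
    if (is.null(signs)) stop("sign_filter requires a sign table", call. = FALSE)
    keep <- !is.na(signs[intermediaries]) & signs[intermediaries] == sign_filter
    intermediaries <- intermediaries[keep]
  }
  g <- expand.grid(source = sources, intermediary = intermediaries,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  if (nrow(g) == 0) {
    return(data.frame(source = character(0), intermediary = character(0),
                      target = character(0), strength = numeric(0)))
  }
  g$target <- target
  g$strength <- P[cbind(g$source, g$intermediary)] *
    P[cbind(g$intermediary, rep(target, nrow(g)))]
  g <- g[order(-g$strength, g$intermediary, g$source), , drop = FALSE]
  if (per_intermediary)
    g <- g[!duplicated(g$intermediary), , drop = FALSE]
  g <- utils::head(g, k)
  rownames(g) <- NULL
  g
}

#' Export ranked pathways to CSV
#'
#' @param pathways output of [rank_pathways()].
#' @param path file path.
#' @export
write_pathways_csv <- function(pathways, path) {
  utils::write.csv(pathways, path, row.names = FALSE)
  invisible(pathways)
}
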