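# All permutations of 1..n (exhaustive oracle for the assignment solver).
all_perms <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) cbind(k, sub + (sub >= k))))
}

# Two-cell fixture: a -> b with 5 synapses.
tiny_connectome <- function() {
  connectome(data.frame(id = c("a", "b"), type = c("A", "B")),
             data.frame(pre = "a", post = "b", count = 5))
}

# Random dense-ish connectome in which every cell has at least one input
# synapse, plus an injective per-type lattice assignment of every cell.
random_connectome <- function(n_cells = 60, n_types = 5, seed = 1,
                              rate = 0.4) {
  set.seed(seed)
  types <- paste0("T", seq_len(n_types))
  cells <- data.frame(id = sprintf("c%03d", seq_len(n_cells)),
                      type = rep(types, length.out = n_cells),
                      stringsAsFactors = FALSE)
  ed <- expand.grid(pre = cells$id, post = cells$id,
                    stringsAsFactors = FALSE)
  ed$count <- stats::rpois(nrow(ed), rate)
  ed <- ed[ed$count > 0, , drop = FALSE]
  missing_in <- setdiff(cells$id, ed$post)
  if (length(missing_in) > 0)
    ed <- rbind(ed, data.frame(pre = sample(cells$id, length(missing_in),
                                            replace = TRUE),
                               post = missing_in, count = 1))
  conn <- connectome(cells, ed)
  assigns <- lapply(types, function(ty) {
    ids <- cells_of_type(conn, ty)
    lattice_assignment(ids, seq_along(ids) %% 7, seq_along(ids) %/% 7,
                       type = ty)
  })
  names(assigns) <- types
  list(conn = conn, assigns = assigns, types = types)
}
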