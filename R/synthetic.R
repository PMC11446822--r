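#' Configuration for the synthetic connectome generator
#'
#' The generator emulates the spatial and statistical structure the analysis
#' assumes: a hexagonal lattice of columns with one cell of each hexel type
#' per column; oriented target cells (Dm3/TmY-like) receiving synapses from
#' `k` collinear columns of a designated source hexel type along a cardinal
#' axis; intermediary cells relaying hexel input from columns at
#' longitudinal offsets beyond the bar (end-zone disynaptic pathways); a
#' signed type-to-type circuit between target types with a spatial kernel;
#' and optional spurious background synapses.
#'
#' @param n_p,n_q lattice extent: columns at p in 0..n_p-1, q in 0..n_q-1.
#' @param roster hexel-type roster; one cell of each per column.
#' @param anchor_type anchored hexel type (assignment input, never inferred).
#' @param chain assignment chain, as in [chain_assign()].
#' @param coupling_lambda mean same-column synapse count between each chain
#'   pair of hexel types (both directions); carries the assignment signal.
#' @param targets list of target-type specs, each a list with `label`,
#'   `axis` ("v", "p" or "q"), `k` (bar length in columns), `lambda` (mean
#'   synapses per contacted column), `n_cells`, and optionally `source_type`
#'   (default "Tm1"), `jitter_sd` (centre jitter, columns, default 0) and
#'   `sign` (presumed sign, default "unknown").
#' @param intermediaries list of intermediary specs, each a list with
#'   `label`, `target_label`, `offsets` (longitudinal column offsets along
#'   the target's axis, relative to the target centre), `lambda`, and
#'   optionally `source_type` and `sign`.  One intermediary cell is created
#'   per (target cell, offset); intermediary cells get no lattice location.
#' @param circuit data.frame of intended type-level edges with columns
#'   `pre`, `post`, and optionally `rho` (spatial kernel radius in columns,
#'   default 1) and `lambda` (default 8): every pre cell synapses onto every
#'   post cell whose true centre lies within `rho`.
#' @param background_rate probability of a spurious unit-count synapse per
#'   ordered cell pair.
#' @param fixed_counts if TRUE, all intended counts equal `round(lambda)`
#'   deterministically; if FALSE (default) counts are Poisson(lambda)
#'   truncated below at 1, so intended topology is never lost.
#' @param seed integer seed; all randomness derives from it, with separate
#'   streams per generation stage so enabling noise does not move bars.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_p = 13, n_q = 13,
                             roster = hexel_roster(),
                             anchor_type = "Mi1",
                             chain = default_chain(roster, anchor_type),
                             coupling_lambda = 10,
                             targets = list(),
                             intermediaries = list(),
                             circuit = NULL,
                             background_rate = 0,
                             fixed_counts = FALSE,
                             seed = 1) {
  stopifnot(n_p >= 1, n_q >= 1, coupling_lambda > 0,
            background_rate >= 0, background_rate <= 1)
  for (tg in targets) {
    stopifnot(!is.null(tg$label), tg$k >= 1, tg$lambda > 0,
              tg$axis %in% c("v", "p", "q"))
  }
  structure(list(n_p = as.integer(n_p), n_q = as.integer(n_q),
                 roster = roster, anchor_type = anchor_type, chain = chain,
                 coupling_lambda = coupling_lambda, targets = targets,
                 intermediaries = intermediaries, circuit = circuit,
                 background_rate = background_rate,
                 fixed_counts = fixed_counts, seed = as.integer(seed)),
            class = "generator_config")
}

# Count draw for intended edges: Poisson(lambda) truncated below at 1,
# or deterministic round(lambda) when fixed.
draw_counts <- function(n, lambda, fixed) {
  if (fixed) rep(max(1, round(lambda)), n) else pmax(1L, stats::rpois(n, lambda))
}

hexel_id <- function(type, p, q) sprintf("%s:%d,%d", type, p, q)

#' Generate a synthetic connectome with ground truth
#'
#' Builds the connectome described by a [generator_config()]: hexel cells
#' (one per type per column) with same-column coupling synapses along the
#' assignment chain, target cells with collinear input bars, per-offset
#' intermediary cells, target-type circuit synapses for cell pairs within
#' the kernel radius, and background noise.  Bars that would leave the
#' lattice are truncated and flagged in the ground truth.
#'
#' @param config a [generator_config()].
#' @return list with elements `conn` (a [connectome]), `assignments`
#'   (named list of [lattice_assignment]s, one per hexel type: the anchored
#'   positions, i.e. the generator's ground truth placement), `truth`
#'   (list: `targets` data.frame with true centre/axis/k/truncation per
#'   target cell, `bars` data.frame of true bar columns per cell, `wiring`
#'   intended type-level edges with signs, `signs` a [type_sign_table]),
#'   and `config`.
#' @export
generate_connectome <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cols <- expand.grid(p = 0:(config$n_p - 1), q = 0:(config$n_q - 1))
  cols <- cols[order(cols$p, cols$q), ]
  n_cols <- nrow(cols)

  # hexel cells and their anchored lattice positions
  cells <- do.call(rbind, lapply(config$roster, function(ty)
    data.frame(id = hexel_id(ty, cols$p, cols$q), type = ty,
               stringsAsFactors = FALSE)))
  assignments <- stats::setNames(lapply(config$roster, function(ty)
    lattice_assignment(hexel_id(ty, cols$p, cols$q), cols$p, cols$q,
                       type = ty)), config$roster)

  edges <- list()

  # stage 1: same-column coupling along the assignment chain
  set.seed(config$seed + 1L)
  for (step in config$chain) {
    tgt <- step[[1]]; ref <- step[[2]]
    ids_t <- hexel_id(tgt, cols$p, cols$q)
    ids_r <- hexel_id(ref, cols$p, cols$q)
    edges[[length(edges) + 1]] <- data.frame(
      pre = c(ids_t, ids_r), post = c(ids_r, ids_t),
      count = draw_counts(2 * n_cols, config$coupling_lambda,
                          config$fixed_counts),
      stringsAsFactors = FALSE)
  }

  # stage 2: target cells with collinear bars
  set.seed(config$seed + 2L)
  truth_targets <- list()
  truth_bars <- list()
  for (tg in config$targets) {
    k <- tg$k
    src <- if (is.null(tg$source_type)) "Tm1" else tg$source_type
    jit <- if (is.null(tg$jitter_sd)) 0 else tg$jitter_sd
    step <- hex_axis_step(tg$axis)
    offs <- (0:(k - 1)) - floor((k - 1) / 2)
    # keep intended bars and end-zone pathways inside the lattice
    im_offs <- unlist(lapply(config$intermediaries, function(im)
      if (identical(im$target_label, tg$label)) im$offsets else NULL))
    reach <- c(offs, im_offs)
    margin_p <- max(abs(reach * step[1]))
    margin_q <- max(abs(reach * step[2]))
    ok <- cols$p >= margin_p & cols$p <= config$n_p - 1 - margin_p &
      cols$q >= margin_q & cols$q <= config$n_q - 1 - margin_q
    eligible <- which(if (any(ok)) ok else rep(TRUE, n_cols))
    pick <- eligible[sample.int(length(eligible), tg$n_cells, replace = TRUE)]
    ctr_p <- cols$p[pick] + round(stats::rnorm(tg$n_cells, 0, jit))
    ctr_q <- cols$q[pick] + round(stats::rnorm(tg$n_cells, 0, jit))
    ids <- sprintf("%s#%03d", tg$label, seq_len(tg$n_cells))
    cells <- rbind(cells, data.frame(id = ids, type = tg$label,
                                     stringsAsFactors = FALSE))
    for (i in seq_len(tg$n_cells)) {
      bp <- ctr_p[i] + offs * step[1]
      bq <- ctr_q[i] + offs * step[2]
      inside <- bp >= 0 & bp <= config$n_p - 1 & bq >= 0 & bq <= config$n_q - 1
      truth_targets[[length(truth_targets) + 1]] <- data.frame(
        id = ids[i], type = tg$label, axis = tg$axis, k = k,
        centre_p = ctr_p[i], centre_q = ctr_q[i], source_type = src,
        truncated = any(!inside), stringsAsFactors = FALSE)
      if (!any(inside)) next
      truth_bars[[length(truth_bars) + 1]] <- data.frame(
        id = ids[i], p = bp[inside], q = bq[inside], stringsAsFactors = FALSE)
      edges[[length(edges) + 1]] <- data.frame(
        pre = hexel_id(src, bp[inside], bq[inside]), post = ids[i],
        count = draw_counts(sum(inside), tg$lambda, config$fixed_counts),
        stringsAsFactors = FALSE)
    }
  }
  truth_targets <- if (length(truth_targets) > 0)
    do.call(rbind, truth_targets) else NULL
  truth_bars <- if (length(truth_bars) > 0) do.call(rbind, truth_bars) else NULL

  # stage 3: intermediary cells relaying end-zone input
  set.seed(config$seed + 3L)
  for (im in config$intermediaries) {
    src <- if (is.null(im$source_type)) "Tm1" else im$source_type
    tcells <- truth_targets[truth_targets$type == im$target_label, ,
                            drop = FALSE]
    for (i in seq_len(nrow(tcells))) {
      step <- hex_axis_step(tcells$axis[i])
      for (d in im$offsets) {
        sp <- tcells$centre_p[i] + d * step[1]
        sq <- tcells$centre_q[i] + d * step[2]
        if (sp < 0 || sp > config$n_p - 1 || sq < 0 || sq > config$n_q - 1)
          next
        iid <- sprintf("%s@%s%+d", im$label, tcells$id[i], d)
        cells <- rbind(cells, data.frame(id = iid, type = im$label,
                                         stringsAsFactors = FALSE))
        edges[[length(edges) + 1]] <- data.frame(
          pre = c(hexel_id(src, sp, sq), iid),
          post = c(iid, tcells$id[i]),
          count = draw_counts(2, im$lambda, config$fixed_counts),
          stringsAsFactors = FALSE)
      }
    }
  }

  # stage 4: target-type circuit with spatial kernel
  set.seed(config$seed + 4L)
  wiring <- NULL
  if (!is.null(config$circuit) && nrow(config$circuit) > 0) {
    circ <- as.data.frame(config$circuit, stringsAsFactors = FALSE)
    if (is.null(circ$rho)) circ$rho <- 1
    if (is.null(circ$lambda)) circ$lambda <- 8
    wiring <- circ[, c("pre", "post")]
    for (r in seq_len(nrow(circ))) {
      pre_c <- truth_targets[truth_targets$type == circ$pre[r], , drop = FALSE]
      post_c <- truth_targets[truth_targets$type == circ$post[r], ,
                              drop = FALSE]
      if (nrow(pre_c) == 0 || nrow(post_c) == 0) next
      pair <- expand.grid(a = seq_len(nrow(pre_c)), b = seq_len(nrow(post_c)))
      d <- hex_dist(pre_c$centre_p[pair$a], pre_c$centre_q[pair$a],
                    post_c$centre_p[pair$b], post_c$centre_q[pair$b])
      keep <- which(d <= circ$rho[r] &
                      pre_c$id[pair$a] != post_c$id[pair$b])
      if (length(keep) == 0) next
      edges[[length(edges) + 1]] <- data.frame(
        pre = pre_c$id[pair$a[keep]], post = post_c$id[pair$b[keep]],
        count = draw_counts(length(keep), circ$lambda[r],
                            config$fixed_counts),
        stringsAsFactors = FALSE)
    }
  }

  # stage 5: background noise (spurious unit-count synapses)
  set.seed(config$seed + 5L)
  if (config$background_rate > 0) {
    n_cells_tot <- nrow(cells)
    n_noise <- stats::rbinom(1, n_cells_tot^2, config$background_rate)
    if (n_noise > 0) {
      pre_i <- sample.int(n_cells_tot, n_noise, replace = TRUE)
      post_i <- sample.int(n_cells_tot, n_noise, replace = TRUE)
      edges[[length(edges) + 1]] <- data.frame(
        pre = cells$id[pre_i], post = cells$id[post_i], count = 1,
        stringsAsFactors = FALSE)
    }
  }

  # presumed signs: targets and intermediaries as configured, hexels unknown
  sign_types <- character(0); sign_vals <- character(0)
  for (tg in config$targets) {
    sign_types <- c(sign_types, tg$label)
    sign_vals <- c(sign_vals, if (is.null(tg$sign)) "unknown" else tg$sign)
  }
  for (im in config$intermediaries) {
    sign_types <- c(sign_types, im$label)
    sign_vals <- c(sign_vals, if (is.null(im$sign)) "unknown" else im$sign)
  }
  signs <- type_sign_table(sign_types, sign_vals)
  if (!is.null(wiring))
    wiring$sign <- vapply(wiring$pre, function(t)
      if (t %in% names(signs)) unname(signs[t]) else "unknown", character(1))

  conn <- connectome(cells, do.call(rbind, edges))
  list(conn = conn, assignments = assignments,
       truth = list(targets = truth_targets, bars = truth_bars,
                    wiring = wiring, signs = signs),
       config = config)
}

#' Closed-form aspect ratio of a k-column collinear bar
#'
#' A bar of `k` equally weighted collinear hexels spaced one lattice
#' constant apart has longitudinal variance `(k^2 - 1) a^2 / 12` plus the
#' hexagon correction `5 a^2 / 36` on both axes, giving aspect
#' `sqrt((3 k^2 + 2) / 5)`.
#'
#' @param k bar length in columns.
#' @export
bar_aspect_theory <- function(k) sqrt((3 * k^2 + 2) / 5)

#' End-to-end recovery metrics on a generated bundle
#'
#' Re-runs the analysis pipeline on a synthetic connectome and scores it
#' against the generator's ground truth: lattice assignment accuracy (via
#' [chain_assign()] from the anchor), per-cell receptive-field ellipse
#' orientation error (axial degrees) and aspect against the closed form
#' [bar_aspect_theory()], centre hit rate ([centre_of_map()] vs true
#' centre), and wiring-diagram edge precision/recall against the intended
#' circuit at the given input-fraction threshold.  Truncated-bar cells are
#' excluded from the geometric metrics.
#'
#' @param bundle output of [generate_connectome()].
#' @param threshold wiring threshold (default 0.03).
#' @param use_true_assignment if TRUE skip re-assignment and use the
#'   generator's anchored positions (isolates map geometry from assignment).
#' @return list of metrics; per-cell detail in element `cells`.
#' @export
recovery_report <- function(bundle, threshold = 0.03,
                            use_true_assignment = FALSE) {
  conn <- bundle$conn
  config <- bundle$config
  anchor <- bundle$assignments[[config$anchor_type]]
  if (use_true_assignment) {
    rec <- bundle$assignments
    acc <- NA_real_
  } else {
    rec <- suppressMessages(chain_assign(conn, anchor, config$chain))
    hits <- 0L; tot <- 0L
    for (ty in setdiff(config$roster, config$anchor_type)) {
      tru <- bundle$assignments[[ty]]
      est <- rec[[ty]]
      pos <- match(tru$id, est$id)
      hits <- hits + sum(!is.na(pos) & est$p[pos] == tru$p &
                           est$q[pos] == tru$q)
      tot <- tot + nrow(tru)
    }
    acc <- hits / tot
  }

  tt <- bundle$truth$targets
  cells_out <- NULL
  if (!is.null(tt)) {
    ok <- which(!tt$truncated)
    res <- lapply(ok, function(i) {
      src_assign <- rec[[tt$source_type[i]]]
      m <- suppressMessages(
        mono_map_cell(conn, src_assign, tt$source_type[i], tt$id[i]))
      if (nrow(m) == 0) return(NULL)
      e <- ellipse_fit(m)
      ctr <- centre_of_map(m)
      data.frame(id = tt$id[i], type = tt$type[i],
                 orientation_error = axial_diff_deg(e$orientation,
                                                hex_axis_angle(tt$axis[i])),
                 aspect = e$aspect,
                 aspect_theory = bar_aspect_theory(tt$k[i]),
                 centre_hit = (ctr[1] == tt$centre_p[i] &&
                                 ctr[2] == tt$centre_q[i]),
                 stringsAsFactors = FALSE)
    })
    cells_out <- do.call(rbind, res)
  }

  wire <- list(precision = NA_real_, recall = NA_real_)
  if (!is.null(bundle$truth$wiring)) {
    P_type <- input_fractions(type_matrix(conn), quiet = TRUE)
    target_types <- unique(tt$type)
    wd <- build_wiring(P_type, target_types, threshold = threshold,
                       signs = bundle$truth$signs)
    wire <- wiring_edge_scores(wd, bundle$truth$wiring)
  }

  list(assignment_accuracy = acc,
       n_cells_scored = if (is.null(cells_out)) 0L else nrow(cells_out),
       median_orientation_error_deg = if (is.null(cells_out)) NA_real_
       else stats::median(cells_out$orientation_error),
       median_aspect = if (is.null(cells_out)) NA_real_
       else stats::median(cells_out$aspect),
       median_aspect_error = if (is.null(cells_out)) NA_real_
       else stats::median(abs(cells_out$aspect - cells_out$aspect_theory)),
       centre_hit_rate = if (is.null(cells_out)) NA_real_
       else mean(cells_out$centre_hit),
       wiring_precision = wire$precision,
       wiring_recall = wire$recall,
       cells = cells_out)
}

#' End-zone signature of disynaptic pathways
#'
#' For every non-truncated target cell of a bundle with intermediaries
#' configured, compares the longitudinal 1D-projection support of the
#' monosynaptic map with that of the disynaptic map through the
#' intermediary type.  End-zone intermediaries make the disynaptic map
#' extend beyond the predicted classical receptive field, so its
#' longitudinal support strictly exceeds the monosynaptic support.
#'
#' @param bundle output of [generate_connectome()] with at least one
#'   intermediary spec.
#' @return data.frame per target cell: `id`, `mono_extent`, `di_extent`
#'   (largest absolute longitudinal bin coordinate with non-zero mass).
#' @export
endzone_signature <- function(bundle) {
  conn <- bundle$conn
  stopifnot(length(bundle$config$intermediaries) >= 1)
  P <- input_fractions(conn$W, quiet = TRUE)
  tt <- bundle$truth$targets
  out <- list()
  for (im in bundle$config$intermediaries) {
    src <- if (is.null(im$source_type)) "Tm1" else im$source_type
    tc <- tt[tt$type == im$target_label & !tt$truncated, , drop = FALSE]
    for (i in seq_len(nrow(tc))) {
      assign_src <- bundle$assignments[[src]]
      mono <- suppressMessages(
        mono_map_cell(conn, assign_src, src, tc$id[i]))
      di <- di_map_cell(conn, assign_src, src, im$label, tc$id[i], P = P)
      if (nrow(mono) == 0 || nrow(di) == 0) {
        message("cell ", tc$id[i], " lacks a mono or di map; skipped")
        next
      }
      ctr <- c(tc$centre_p[i], tc$centre_q[i])
      out[[length(out) + 1]] <- data.frame(
        id = tc$id[i], intermediary = im$label,
        mono_extent = projection_extent(
          project_cardinal(shift_map(mono, -ctr[1], -ctr[2]), tc$axis[i])),
        di_extent = projection_extent(
          project_cardinal(shift_map(di, -ctr[1], -ctr[2]), tc$axis[i])),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Reference study configurations
#'
#' Canonical generator settings used for the package's recovery studies.
#' `"bar_recovery"`: 200 oriented-bar cells (k = 3) split over the three
#' cardinal axes with Poisson synapse counts (lambda = 8), a cyclic signed
#' circuit between the three target types, end-zone intermediaries on the
#' v-type, and mild background noise (2e-4 spurious unit synapses per
#' ordered cell pair).  `"zero_noise"`: the same layout with deterministic
#' counts, no jitter and no background, for exact-recovery checks.
#' `"endzone"`: a single target type with end-zone intermediaries at
#' longitudinal offsets ±2, ±3 columns and no background, isolating the
#' disynaptic-beyond-monosynaptic signature.
#'
#' @param kind which study.
#' @param seed integer seed.
#' @return a [generator_config()].
#' @export
study_config <- function(kind = c("bar_recovery", "zero_noise", "endzone"),
                         seed = 1) {
  kind <- match.arg(kind)
  dm3 <- function(n_cells) list(
    list(label = "Dm3v", axis = "v", k = 3, lambda = 8, n_cells = n_cells[1],
         sign = "inhibitory"),
    list(label = "Dm3p", axis = "p", k = 3, lambda = 8, n_cells = n_cells[2],
         sign = "inhibitory"),
    list(label = "Dm3q", axis = "q", k = 3, lambda = 8, n_cells = n_cells[3],
         sign = "inhibitory"))
  circuit <- data.frame(pre = c("Dm3v", "Dm3p", "Dm3q"),
                        post = c("Dm3p", "Dm3q", "Dm3v"),
                        rho = 1, lambda = 8)
  t2a <- list(label = "T2a", target_label = "Dm3v",
              offsets = c(-3, -2, 2, 3), lambda = 8, sign = "excitatory")
  switch(kind,
         bar_recovery = generator_config(
           n_p = 15, n_q = 15, targets = dm3(c(67, 67, 66)),
           intermediaries = list(t2a), circuit = circuit,
           background_rate = 2e-4, fixed_counts = FALSE, seed = seed),
         zero_noise = generator_config(
           n_p = 15, n_q = 15, targets = dm3(c(67, 67, 66)),
           intermediaries = list(t2a), circuit = circuit,
           background_rate = 0, fixed_counts = TRUE, seed = seed),
         endzone = generator_config(
           n_p = 15, n_q = 15,
           targets = list(list(label = "Dm3v", axis = "v", k = 3,
                               lambda = 8, n_cells = 50)),
           intermediaries = list(t2a),
           background_rate = 0, fixed_counts = FALSE, seed = seed))
}
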