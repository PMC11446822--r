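#' End-to-end pipeline on a synthetic or loaded connectome
#'
#' Runs the full analysis in order — lattice assignment from the anchor,
#' input fractions, per-cell monosynaptic maps and centres, align/crop/
#' average, ellipse fits, 1D projections, pathway ranking, wiring diagram,
#' recovery metrics — and writes every artifact as CSV into `out_dir`
#' together with a JSON manifest recording the configuration, seed and
#' package version.  Deterministic stages are bit-identical across reruns
#' with identical inputs.
#'
#' @param config list with elements: either `bundle` (a
#'   [generate_connectome()] result) or `generator` (a [generator_config()]
#'   to run first); `window_radius` (default 8); `wiring_threshold`
#'   (default 0.03); `out_dir` output directory.
#' @return invisibly, the path of the artifact directory; artifacts:
#'   `cells.csv`/`edges.csv`, `assignment_<type>.csv`, `pathways_<type>.csv`,
#'   `map_mean_<type>.csv`, `ellipses_<type>.csv`,
#'   `projection_<type>_<axis>.csv`, `wiring.csv`, `wiring.dot`,
#'   `recovery.csv`, `manifest.json`.
#' @export
run_pipeline <- function(config) {
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir is required", call. = FALSE)
  window_radius <- if (is.null(config$window_radius)) 8 else
    config$window_radius
  threshold <- if (is.null(config$wiring_threshold)) 0.03 else
    config$wiring_threshold
  bundle <- config$bundle
  if (is.null(bundle)) {
    if (is.null(config$generator))
      stop("config needs either 'bundle' or 'generator'", call. = FALSE)
    bundle <- generate_connectome(config$generator)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  conn <- bundle$conn
  gcfg <- bundle$config

  write_connectome(conn, file.path(out_dir, "cells.csv"),
                   file.path(out_dir, "edges.csv"))

  # assignment
  anchor <- bundle$assignments[[gcfg$anchor_type]]
  assigns <- suppressMessages(chain_assign(conn, anchor, gcfg$chain))
  for (ty in names(assigns))
    write_assignment_csv(assigns[[ty]],
                         file.path(out_dir, paste0("assignment_", ty, ".csv")))

  # fractions and pathway ranking
  P_cell <- input_fractions(conn$W, quiet = TRUE)
  P_type <- input_fractions(type_matrix(conn), quiet = TRUE)
  tt <- bundle$truth$targets
  target_types <- if (is.null(tt)) character(0) else unique(tt$type)
  for (ty in target_types) {
    pw <- rank_pathways(P_type, ty, sources = gcfg$roster)
    write_pathways_csv(pw, file.path(out_dir, paste0("pathways_", ty, ".csv")))
  }

  # per-cell maps, centres, averages, ellipses, projections
  if (!is.null(tt)) {
    for (ty in target_types) {
      tc <- tt[tt$type == ty & !tt$truncated, , drop = FALSE]
      if (nrow(tc) == 0) next
      src <- tc$source_type[1]
      maps <- list(); centres <- list(); ells <- list()
      for (i in seq_len(nrow(tc))) {
        m <- suppressMessages(
          mono_map_cell(conn, assigns[[src]], src, tc$id[i]))
        if (nrow(m) == 0) next
        maps[[tc$id[i]]] <- m
        centres[[tc$id[i]]] <- centre_of_map(m)
        ells[[tc$id[i]]] <- ellipse_fit(m)
      }
      if (length(maps) == 0) next
      avg <- align_and_average(unname(maps), unname(centres),
                               window_radius = window_radius)
      write_map_csv(avg$mean, file.path(out_dir,
                                        paste0("map_mean_", ty, ".csv")))
      write_ellipses_csv(ells, file.path(out_dir,
                                         paste0("ellipses_", ty, ".csv")))
      ax <- tc$axis[1]
      projs <- lapply(names(maps), function(id) {
        ctr <- centres[[id]]
        project_cardinal(shift_map(maps[[id]], -ctr[1], -ctr[2]), ax)
      })
      write_projection_csv(projection_stats(projs),
                           file.path(out_dir,
                                     paste0("projection_", ty, "_", ax,
                                            ".csv")))
    }
  }

  # wiring diagram over target types
  if (length(target_types) > 0) {
    wd <- build_wiring(P_type, target_types, threshold = threshold,
                       signs = bundle$truth$signs)
    write_wiring_csv(wd, file.path(out_dir, "wiring.csv"))
    write_wiring_dot(wd, file.path(out_dir, "wiring.dot"))
  }

  # recovery metrics
  rep <- recovery_report(bundle, threshold = threshold)
  scalars <- rep[setdiff(names(rep), "cells")]
  utils::write.csv(data.frame(metric = names(scalars),
                              value = unlist(lapply(scalars, function(x)
                                if (is.null(x)) NA else as.numeric(x)))),
                   file.path(out_dir, "recovery.csv"), row.names = FALSE)

  manifest <- list(
    package = "hexelmap",
    version = as.character(utils::packageVersion("hexelmap")),
    r_version = as.character(getRversion()),
    seed = gcfg$seed,
    window_radius = window_radius,
    wiring_threshold = threshold,
    generator = gcfg[setdiff(names(gcfg), c("chain", "targets",
                                            "intermediaries", "circuit"))],
    n_targets = length(gcfg$targets),
    n_intermediaries = length(gcfg$intermediaries))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(out_dir)
}
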