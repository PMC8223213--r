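# End-to-end pipeline: simulate a fixture, analyze a trajectory into
# metrics/composition/lineage/summary files, and plot the time series.
# These functions are the programmatic surface behind the inst/exec/aggtraj
# command-line script; everything is deterministic given inputs and seed.

#' Run configuration for an analysis
#'
#' Validates every knob before any frame is read. The resolved config is
#' echoed as JSON into the output directory for auditability.
#'
#' @param epsilon clustering radius; number (nm) or string with unit
#'   (\code{"15A"}).
#' @param min_points DBSCAN minimum neighborhood size (self-inclusive).
#' @param pbc_mode \code{"minimum-image"} or \code{"none"}.
#' @param cutoff bilayer contact cutoff, nm.
#' @param stride analyze every stride-th frame.
#' @param agg_num_convention \code{"in-aggregates"} or \code{"all"}.
#' @param weighting COM weighting.
#' @param seed integer seed (recorded; analysis itself is deterministic).
#' @return list of class \code{aggtraj_config}.
#' @export
run_config <- function(epsilon = 1.5, min_points = 2,
                       pbc_mode = c("minimum-image", "none"),
                       cutoff = 0.6, stride = 1,
                       agg_num_convention = c("in-aggregates", "all"),
                       weighting = c("geometric", "mass"), seed = 1) {
  pbc_mode <- match.arg(pbc_mode)
  agg_num_convention <- match.arg(agg_num_convention)
  weighting <- match.arg(weighting)
  epsilon <- parse_length_nm(epsilon)
  if (!is.finite(epsilon) || epsilon <= 0) stop("epsilon must be > 0")
  if (!is.finite(cutoff) || cutoff <= 0) stop("cutoff must be > 0")
  if (stride < 1) stop("stride must be >= 1")
  structure(list(epsilon = epsilon, min_points = as.integer(min_points),
                 pbc_mode = pbc_mode, cutoff = cutoff,
                 stride = as.integer(stride),
                 agg_num_convention = agg_num_convention,
                 weighting = weighting, seed = as.integer(seed)),
            class = "aggtraj_config")
}

#' Simulate a preset scenario and write the fixture bundle to disk
#'
#' @param preset preset name (see \code{\link{synthetic_preset}}) or an
#'   explicit \code{\link{synthetic_spec}}.
#' @param path output fixture path.
#' @param seed seed forwarded to the preset.
#' @return the generated \code{aggtraj_bundle}, invisibly.
#' @export
simulate_fixture <- function(preset = "demo", path, seed = 1) {
  spec <- if (inherits(preset, "aggtraj_synthetic_spec")) preset
          else synthetic_preset(preset, seed = seed)
  bun <- generate_planted_trajectory(spec)
  write_fixture(bun, path)
  invisible(bun)
}

#' Analyze a trajectory into metrics, composition, lineage and summary
#'
#' Runs the full observable pipeline on a bundle (or a fixture path):
#' per-frame clustering and metrics, the final-frame composition table, and
#' the focal-aggregate lineage backtracked from the last analyzed frame.
#' Writes \code{metrics.csv}, \code{composition.csv}, \code{lineage.json},
#' \code{summary.txt} and \code{config.json} into \code{out_dir}; outputs
#' are byte-stable across reruns.
#'
#' @param x an \code{aggtraj_bundle} or a native fixture path.
#' @param out_dir output directory (created if missing); NULL to skip
#'   writing.
#' @param config a \code{\link{run_config}}.
#' @return list with \code{$metrics}, \code{$composition},
#'   \code{$lineage} (NULL when the last frame has no aggregate),
#'   \code{$growth} (lineage table or NULL), \code{$summary} (character).
#' @export
analyze_trajectory <- function(x, out_dir = NULL, config = run_config()) {
  bun <- if (inherits(x, "aggtraj_bundle")) x else load_fixture(x)
  topo <- bun$topology
  params <- clustering_params(config$epsilon, config$min_points,
                              pbc_mode = config$pbc_mode)
  metrics <- metric_time_series(bun, params, cutoff = config$cutoff,
                                stride = config$stride,
                                weighting = config$weighting,
                                agg_num_convention = config$agg_num_convention)
  idx <- seq(1, n_frames(bun), by = min(config$stride, n_frames(bun)))
  sets <- lapply(idx, function(i) {
    coms <- com_set(bun$frames[[i]], topo, weighting = config$weighting,
                    pbc_mode = config$pbc_mode)
    dbscan_aggregates(coms, params, topo)
  })
  last <- sets[[length(sets)]]
  comp <- composition_table(last, topo)
  lin <- NULL; growth <- NULL
  if (length(last$aggregates) && length(sets) >= 2) {
    lin <- backtrack(sets, topo)
    growth <- lineage_table(lin)
  }
  tags <- solute_species_tags(topo)
  final <- metrics[nrow(metrics), ]
  summary_lines <- c(
    sprintf("frames analyzed: %d (stride %d)", nrow(metrics),
            config$stride),
    sprintf("final complex ratio: %s", format_full(final$complex_ratio)),
    sprintf("final average aggregation number: %s",
            format_full(final$avg_aggregation_number)),
    sprintf("final contacts: %s",
            paste(sprintf("%s=%s", tags,
                          vapply(paste0("contacts_", tags),
                                 function(cn) as.character(final[[cn]]),
                                 character(1))),
                  collapse = " ")),
    if (!is.null(growth)) {
      nz <- growth[growth$n_gained > 0 | growth$n_lost > 0, ]
      c("focal aggregate growth events (frame, +gained/-lost):",
        if (nrow(nz)) sprintf("  frame %d: +%d/-%d (size %d)", nz$frame,
                              nz$n_gained, nz$n_lost, nz$size)
        else "  none")
    } else "no focal aggregate in the last frame; lineage skipped"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_metrics(metrics, file.path(out_dir, "metrics.csv"))
    write_composition_csv(comp, file.path(out_dir, "composition.csv"))
    if (!is.null(lin)) {
      write_lineage_json(lin, file.path(out_dir, "lineage.json"))
    }
    con <- file(file.path(out_dir, "summary.txt"), open = "wb")
    writeLines(summary_lines, con, sep = "\n")
    close(con)
    jsonlite::write_json(unclass(config),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(metrics = metrics, composition = comp, lineage = lin,
                 growth = growth, summary = summary_lines))
}

#' Plot metric time series and composition bars
#'
#' Writes time-series figures (complex ratio, average aggregation number,
#' contact counts) and, when a composition table is given, a composition
#' bar chart. Plot failures never touch the metrics files: this function
#' only reads.
#'
#' @param metrics metric series data.frame or a metrics.csv path.
#' @param out_dir directory for the figures.
#' @param composition optional composition table or composition.csv path.
#' @param device \code{"pdf"} (default) or \code{"png"}.
#' @return character vector of files written, invisibly.
#' @export
plot_metrics <- function(metrics, out_dir, composition = NULL,
                         device = c("pdf", "png")) {
  device <- match.arg(device)
  if (is.character(metrics)) {
    metrics <- utils::read.csv(metrics, check.names = FALSE)
  }
  if (!nrow(metrics)) stop("empty metric series; nothing to plot")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  save_one <- function(p, name) {
    f <- file.path(out_dir, paste0(name, ".", device))
    ggplot2::ggsave(f, p, width = 6, height = 4, dpi = 150)
    written <<- c(written, f)
  }
  save_one(
    ggplot2::ggplot(metrics,
                    ggplot2::aes(x = time_ns, y = complex_ratio)) +
      ggplot2::geom_line() + ggplot2::ylim(0, 1) +
      ggplot2::labs(x = "time (ns)", y = "fraction of molecules in complex"),
    "complex_ratio")
  save_one(
    ggplot2::ggplot(metrics,
                    ggplot2::aes(x = time_ns,
                                 y = avg_aggregation_number)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time (ns)", y = "average aggregation number"),
    "aggregation_number")
  ccols <- grep("^contacts_", names(metrics), value = TRUE)
  if (length(ccols) && !all(is.na(metrics[, ccols]))) {
    long <- do.call(rbind, lapply(ccols, function(cn) {
      data.frame(time_ns = metrics$time_ns, species = sub("contacts_", "", cn),
                 contacts = metrics[[cn]])
    }))
    save_one(
      ggplot2::ggplot(long, ggplot2::aes(x = time_ns,
                                         y = contacts,
                                         colour = species)) +
        ggplot2::geom_line() +
        ggplot2::labs(x = "time (ns)", y = "molecules in bilayer contact"),
      "contacts")
  }
  if (!is.null(composition)) {
    if (is.character(composition)) {
      composition <- utils::read.csv(composition, check.names = FALSE)
    }
    ncols <- grep("^n_", names(composition), value = TRUE)
    composition$class <- apply(composition[ncols], 1, paste, collapse = ":")
    save_one(
      ggplot2::ggplot(composition,
                      ggplot2::aes(x = class, y = count)) +
        ggplot2::geom_col() +
        ggplot2::labs(x = paste(sub("n_", "", ncols), collapse = ":"),
                      y = "aggregates"),
      "composition")
  }
  invisible(written)
}
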