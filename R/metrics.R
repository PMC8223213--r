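# Per-frame observables of the co-assembly state: complex ratio, average
# aggregation number, bilayer contact counts and aggregate composition
# tables, plus their assembly into a per-frame time series.

#' Fraction of molecules in complex
#'
#' The number of molecules belonging to any aggregate (size >= 2 under the
#' default clustering) divided by the total number of solute molecules.
#' Membership counts regardless of species mix: a single-species dimer is
#' in complex, matching the partition the clustering produces. Set
#' \code{mixed_only = TRUE} to count only aggregates containing more than
#' one species.
#'
#' @param aggs an \code{aggtraj_aggregates}.
#' @param total total number of solute molecules (>= 1).
#' @param topo topology; required only for \code{mixed_only}.
#' @param mixed_only count only mixed-species aggregates.
#' @return fraction in [0, 1].
#' @export
complex_ratio <- function(aggs, total, topo = NULL, mixed_only = FALSE) {
  stopifnot(inherits(aggs, "aggtraj_aggregates"), total >= 1)
  groups <- aggs$aggregates
  if (mixed_only) {
    if (is.null(topo)) stop("mixed_only requires the topology")
    sp <- molecule_species(topo)
    groups <- Filter(function(g) {
      length(unique(sp[as.character(g)])) > 1
    }, groups)
  }
  sum(vapply(groups, length, integer(1))) / total
}

#' Average aggregation number
#'
#' Molecules per aggregate, per frame. The default convention divides the
#' number of molecules that are in aggregates by the number of aggregates;
#' the \code{"all"} convention divides the total number of solute molecules
#' (free included) by the number of aggregates. Returns 0 when no
#' aggregates exist (documented convention; the quantity is otherwise
#' undefined).
#'
#' @param aggs an \code{aggtraj_aggregates}.
#' @param convention \code{"in-aggregates"} (default) or \code{"all"}.
#' @param total total solute molecules; required for \code{"all"}.
#' @return mean molecules per aggregate.
#' @export
average_aggregation_number <- function(aggs,
                                       convention = c("in-aggregates", "all"),
                                       total = NULL) {
  convention <- match.arg(convention)
  k <- length(aggs$aggregates)
  if (k == 0) return(0)
  if (convention == "in-aggregates") {
    sum(vapply(aggs$aggregates, length, integer(1))) / k
  } else {
    if (is.null(total)) total <- aggs$n_molecules
    total / k
  }
}

#' Per-species counts of solute molecules in contact with the bilayer
#'
#' A solute molecule is in contact iff any of its particles lies within the
#' cutoff (minimum-image) of any lipid particle; each molecule is counted
#' at most once.
#'
#' @param fr an \code{aggtraj_frame}.
#' @param topo topology with at least one lipid species.
#' @param cutoff contact distance, nm (> 0). Default 0.6 nm, a common
#'   heavy-atom/coarse-grained contact range; the criterion is
#'   configuration, not physics, so sensitivity should be checked.
#' @param pbc_mode minimum-image (default) or naive distances.
#' @return named integer vector, one count per solute species (registry
#'   order).
#' @export
bilayer_contacts <- function(fr, topo, cutoff = 0.6,
                             pbc_mode = c("minimum-image", "none")) {
  pbc_mode <- match.arg(pbc_mode)
  if (cutoff <= 0) stop("cutoff must be > 0")
  lip_rows <- select_particles(topo, molecules = lipid_molecules(topo))
  if (!length(lip_rows)) stop("no lipid particles; cannot count contacts")
  tags <- solute_species_tags(topo)
  lipxyz <- fr$coords[lip_rows, , drop = FALSE]
  out <- stats::setNames(integer(length(tags)), tags)
  p <- topo$particles
  for (tg in tags) {
    mols <- unique(p$molecule[p$species == tg])
    hit <- 0L
    for (m in mols) {
      rows <- which(p$molecule == m)
      d <- cross_distances(fr$coords[rows, , drop = FALSE], lipxyz,
                           fr$box, pbc_mode)
      if (any(d <= cutoff)) hit <- hit + 1L
    }
    out[tg] <- hit
  }
  out
}

#' Aggregate composition table for one frame
#'
#' Bins every aggregate by its exact per-species composition and every free
#' molecule into the corresponding one-molecule class, e.g. (1, 0) for a
#' free molecule of the first species and (0, 1) for the second. The
#' table's mass balance (sum of count x class size = total solutes) holds
#' by construction.
#'
#' @param aggs an \code{aggtraj_aggregates}.
#' @param topo topology (two or more solute species expected).
#' @return data.frame of class \code{aggtraj_composition_table} with one
#'   column \code{n_<tag>} per solute species, a \code{count} column and a
#'   \code{time_ns} column.
#' @export
composition_table <- function(aggs, topo) {
  tags <- solute_species_tags(topo)
  classes <- lapply(aggs$aggregates, function(g) {
    unlist(composition(g, topo)[1, tags])
  })
  sp <- molecule_species(topo)
  for (m in aggs$noise) {
    cls <- stats::setNames(integer(length(tags)), tags)
    cls[sp[as.character(m)]] <- 1L
    classes <- c(classes, list(cls))
  }
  if (!length(classes)) {
    tab <- as.data.frame(stats::setNames(
      rep(list(integer(0)), length(tags) + 1),
      c(paste0("n_", tags), "count")))
  } else {
    keys <- vapply(classes, paste, character(1), collapse = ":")
    uk <- unique(keys)
    tab <- do.call(rbind, lapply(uk, function(k) {
      cls <- classes[[match(k, keys)]]
      row <- as.data.frame(as.list(stats::setNames(as.integer(cls),
                                                   paste0("n_", tags))))
      row$count <- sum(keys == k)
      row
    }))
    tab <- tab[do.call(order, unname(tab[paste0("n_", tags)])), ,
               drop = FALSE]
    rownames(tab) <- NULL
  }
  tab$time_ns <- rep(aggs$time, nrow(tab))
  class(tab) <- c("aggtraj_composition_table", "data.frame")
  tab
}

#' Per-frame metric time series for a trajectory
#'
#' For each analyzed frame: clusters solute COMs, then reports the number
#' of aggregates, average aggregation number, complex ratio, free-molecule
#' counts per species and (when the topology contains lipids) bilayer
#' contact counts per species.
#'
#' @param bun an \code{aggtraj_bundle}.
#' @param params \code{\link{clustering_params}}.
#' @param cutoff bilayer contact cutoff, nm.
#' @param stride analyze every stride-th frame (>= 1). A stride larger than
#'   the trajectory yields a single-frame analysis with a warning.
#' @param weighting COM weighting, \code{"geometric"} or \code{"mass"}.
#' @param agg_num_convention passed to
#'   \code{\link{average_aggregation_number}}.
#' @return data.frame of class \code{aggtraj_metric_series}: columns frame,
#'   time_ns, n_aggregates, avg_aggregation_number, complex_ratio,
#'   free_<tag>... and contacts_<tag>... (NA without lipids).
#' @export
metric_time_series <- function(bun, params = clustering_params(),
                               cutoff = 0.6, stride = 1,
                               weighting = c("geometric", "mass"),
                               agg_num_convention = c("in-aggregates", "all")) {
  weighting <- match.arg(weighting)
  agg_num_convention <- match.arg(agg_num_convention)
  stopifnot(inherits(bun, "aggtraj_bundle"), stride >= 1)
  nf <- n_frames(bun)
  if (stride > nf) {
    warning("stride ", stride, " exceeds the ", nf,
            " frames; analyzing the first frame only")
    stride <- nf
  }
  idx <- seq(1, nf, by = stride)
  topo <- bun$topology
  tags <- solute_species_tags(topo)
  has_lipids <- length(lipid_molecules(topo)) > 0
  total <- length(solute_molecules(topo))
  sp <- molecule_species(topo)
  rows <- lapply(idx, function(i) {
    fr <- bun$frames[[i]]
    coms <- com_set(fr, topo, weighting = weighting,
                    pbc_mode = params$pbc_mode)
    aggs <- dbscan_aggregates(coms, params, topo)
    row <- data.frame(
      frame = fr$index, time_ns = fr$time,
      n_aggregates = length(aggs$aggregates),
      avg_aggregation_number =
        average_aggregation_number(aggs, agg_num_convention, total),
      complex_ratio = complex_ratio(aggs, total)
    )
    for (tg in tags) {
      row[[paste0("free_", tg)]] <-
        sum(sp[as.character(aggs$noise)] == tg)
    }
    contacts <- if (has_lipids) {
      bilayer_contacts(fr, topo, cutoff, params$pbc_mode)
    } else stats::setNames(rep(NA_integer_, length(tags)), tags)
    for (tg in tags) row[[paste0("contacts_", tg)]] <- contacts[[tg]]
    row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("aggtraj_metric_series", "data.frame")
  attr(out, "params") <- params
  attr(out, "cutoff") <- cutoff
  attr(out, "weighting") <- weighting
  attr(out, "agg_num_convention") <- agg_num_convention
  out
}
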