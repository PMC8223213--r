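# Aggregation-evolution tracking: the biggest aggregate of the last frame
# is identified and backtracked frame by frame; in each earlier frame the
# aggregate sharing the most molecules is its predecessor, and the
# membership difference defines the growth or shrink of the focal
# aggregate. Tie-breaks are fully specified so lineages are
# bit-reproducible.

#' Select the focal aggregate of a frame
#'
#' The largest aggregate; size ties are broken toward the aggregate whose
#' smallest member id is smallest.
#'
#' @param aggs an \code{aggtraj_aggregates} (typically the last frame).
#' @return integer vector of member molecule ids (ascending).
#' @export
select_focal <- function(aggs) {
  stopifnot(inherits(aggs, "aggtraj_aggregates"))
  if (!length(aggs$aggregates)) {
    stop("no aggregates in frame ", aggs$frame,
         "; choose a different focal frame")
  }
  # canonical order is already (size desc, smallest member id)
  aggs$aggregates[[1]]
}

#' Predecessor of an aggregate in the previous frame
#'
#' The previous-frame aggregate with maximal membership overlap. Zero
#' overlap with every candidate means the aggregate nucleated from free
#' molecules and there is no predecessor. Overlap ties go to the larger
#' candidate, then to the candidate with the smallest minimum member id.
#'
#' @param current integer molecule ids of the focal aggregate.
#' @param previous an \code{aggtraj_aggregates} for the earlier frame.
#' @return integer member vector of the predecessor, or NULL if none.
#' @export
predecessor <- function(current, previous) {
  stopifnot(inherits(previous, "aggtraj_aggregates"))
  cands <- previous$aggregates
  if (!length(cands) || !length(current)) return(NULL)
  ov <- vapply(cands, function(g) length(intersect(current, g)), integer(1))
  if (max(ov) == 0L) return(NULL)
  sz <- vapply(cands, length, integer(1))
  mn <- vapply(cands, min, numeric(1))
  best <- order(-ov, -sz, mn)[1]
  cands[[best]]
}

#' Backtrack a focal aggregate through a trajectory
#'
#' Walks from the last frame to the first, chaining
#' \code{\link{predecessor}}. Each step records the members gained and lost
#' relative to the predecessor and the signed per-species composition
#' delta. When no predecessor exists the step records nucleation (empty
#' reference set) and the chain continues with an empty set. Steps are
#' reported forward in time.
#'
#' @param sets list of per-frame \code{aggtraj_aggregates}, ordered by
#'   frame (>= 2 frames).
#' @param topo topology, for species deltas.
#' @param focal optional explicit focal member set; defaults to
#'   \code{select_focal} on the last frame.
#' @return object of class \code{aggtraj_lineage}: list with \code{$steps}
#'   (list, one per frame transition, each with frame, time, members,
#'   predecessor, gained, lost, delta), \code{$focal}, \code{$species}.
#' @export
backtrack <- function(sets, topo, focal = NULL) {
  if (length(sets) < 2) stop("need at least 2 frames to backtrack")
  if (is.null(focal)) focal <- select_focal(sets[[length(sets)]])
  tags <- solute_species_tags(topo)
  sp <- molecule_species(topo)
  delta_of <- function(gained, lost) {
    vapply(tags, function(tg) {
      sum(sp[as.character(gained)] == tg) - sum(sp[as.character(lost)] == tg)
    }, integer(1))
  }
  steps <- vector("list", length(sets) - 1)
  cur <- focal
  for (i in seq(length(sets), 2)) {
    pred <- predecessor(cur, sets[[i - 1]])
    predm <- if (is.null(pred)) integer(0) else pred
    gained <- sort(setdiff(cur, predm))
    lost <- sort(setdiff(predm, cur))
    steps[[i - 1]] <- list(
      frame = sets[[i]]$frame, time = sets[[i]]$time,
      members = cur, predecessor = predm,
      gained = gained, lost = lost,
      nucleated = is.null(pred) && length(cur) > 0,
      delta = delta_of(gained, lost)
    )
    cur <- predm
  }
  structure(list(steps = steps, focal = focal, origin = cur,
                 species = tags,
                 first_frame = sets[[1]]$frame,
                 first_time = sets[[1]]$time),
            class = "aggtraj_lineage")
}

#' @export
print.aggtraj_lineage <- function(x, ...) {
  cat("Lineage of a", length(x$focal), "molecule aggregate over",
      length(x$steps), "steps\n")
  growth <- vapply(x$steps, function(s) length(s$gained) - length(s$lost),
                   integer(1))
  nz <- which(growth != 0)
  if (length(nz)) {
    cat("Growth events (frame: net change):",
        paste(sprintf("%d: %+d", vapply(x$steps[nz], `[[`, integer(1), "frame"),
                      growth[nz]), collapse = ", "), "\n")
  } else cat("No membership changes\n")
  invisible(x)
}

#' Lineage growth table
#'
#' One row per frame transition: aggregate size, members gained/lost and
#' per-species signed deltas, suitable for plotting aggregate growth over
#' time.
#'
#' @param lin an \code{aggtraj_lineage}.
#' @return data.frame with columns frame, time_ns, size, n_gained, n_lost,
#'   and delta_<species> per solute species.
#' @export
lineage_table <- function(lin) {
  stopifnot(inherits(lin, "aggtraj_lineage"))
  rows <- lapply(lin$steps, function(s) {
    base <- data.frame(frame = s$frame, time_ns = s$time,
                       size = length(s$members),
                       n_gained = length(s$gained), n_lost = length(s$lost))
    for (tg in lin$species) base[[paste0("delta_", tg)]] <- s$delta[[tg]]
    base
  })
  do.call(rbind, rows)
}

#' Serialize a lineage to JSON
#'
#' One record per step with frame, time_ns, members, predecessor, gained,
#' lost and per-species deltas.
#'
#' @param lin an \code{aggtraj_lineage}.
#' @param path output file path.
#' @return path, invisibly.
#' @export
write_lineage_json <- function(lin, path) {
  stopifnot(inherits(lin, "aggtraj_lineage"))
  recs <- lapply(lin$steps, function(s) {
    list(frame = s$frame, time_ns = s$time,
         members = as.integer(s$members),
         predecessor = as.integer(s$predecessor),
         gained = as.integer(s$gained), lost = as.integer(s$lost),
         nucleated = isTRUE(s$nucleated),
         delta = as.list(s$delta))
  })
  obj <- list(focal = as.integer(lin$focal), species = lin$species,
              steps = recs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
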