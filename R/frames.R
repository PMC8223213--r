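#' A single trajectory snapshot
#'
#' @param index 1-based frame ordinal.
#' @param time time stamp, ns.
#' @param box length-3 orthorhombic box edge lengths, nm (> 0).
#' @param coords n x 3 matrix of particle positions, nm. Stored as given
#'   (possibly wrapped); molecules are made whole only when centers of mass
#'   are computed.
#' @return object of class \code{aggtraj_frame}.
#' @export
frame <- function(index, time, box, coords) {
  coords <- as.matrix(coords)
  box <- as.numeric(box)
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0)) {
    stop("box must be 3 positive edge lengths (orthorhombic), nm")
  }
  if (ncol(coords) != 3) stop("coords must be an n x 3 matrix")
  if (any(!is.finite(coords))) stop("non-finite coordinates in frame ", index)
  structure(list(index = as.integer(index), time = as.numeric(time),
                 box = box, coords = unname(coords)),
            class = "aggtraj_frame")
}

#' Bundle of frames, topology and optional planted ground truth
#'
#' The in-memory form of a trajectory: an ordered list of frames sharing one
#' topology. Synthetic bundles additionally carry \code{ground_truth}, a list
#' with per-frame aggregate labels for every solute molecule (0 = free) and
#' the scripted event log.
#'
#' @param frames list of \code{aggtraj_frame}, ordered by time.
#' @param topology an \code{aggtraj_topology}.
#' @param ground_truth optional list(labels = list of integer vectors named
#'   by molecule id, events = data.frame event log, molecules = molecule ids
#'   the label vectors refer to).
#' @param meta optional named list recorded in the fixture header (seed,
#'   generator spec, ...).
#' @return object of class \code{aggtraj_bundle}.
#' @export
bundle <- function(frames, topology, ground_truth = NULL, meta = list()) {
  stopifnot(inherits(topology, "aggtraj_topology"), length(frames) >= 1)
  np <- nrow(topology$particles)
  for (fr in frames) {
    if (!inherits(fr, "aggtraj_frame")) stop("frames must be aggtraj_frame")
    if (nrow(fr$coords) != np) {
      stop("frame ", fr$index, " has ", nrow(fr$coords),
           " particles but topology has ", np)
    }
  }
  times <- vapply(frames, `[[`, numeric(1), "time")
  if (is.unsorted(times)) stop("frames must be ordered by time")
  if (!is.null(ground_truth)) {
    sol <- solute_molecules(topology)
    if (length(ground_truth$labels) != length(frames)) {
      stop("ground truth must label every frame")
    }
    for (lab in ground_truth$labels) {
      if (length(lab) != length(sol)) {
        stop("ground-truth labels must cover every solute molecule")
      }
    }
    ground_truth$molecules <- sol
  }
  structure(list(frames = frames, topology = topology,
                 ground_truth = ground_truth, meta = meta),
            class = "aggtraj_bundle")
}

#' @export
print.aggtraj_bundle <- function(x, ...) {
  nf <- length(x$frames)
  cat("Trajectory bundle:", nf, "frames,",
      nrow(x$topology$particles), "particles; t =",
      format_full(x$frames[[1]]$time), "-",
      format_full(x$frames[[nf]]$time), "ns\n")
  cat("Ground truth:", if (is.null(x$ground_truth)) "absent" else "present",
      "\n")
  invisible(x)
}

n_frames <- function(b) length(b$frames)
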