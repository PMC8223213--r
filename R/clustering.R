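# Density-based aggregate identification. Molecular centers of mass are
# clustered per frame with DBSCAN on Euclidean (optionally minimum-image)
# distances; each cluster is an aggregate, unclustered molecules are free.
# Defaults follow the co-assembly setting: epsilon 1.5 nm (15 A) and
# min_points 2 with a self-inclusive neighborhood count, for which DBSCAN
# reduces exactly to connected components of the epsilon-graph.

#' Clustering parameters for aggregate identification
#'
#' @param epsilon neighborhood radius; a number in nm or a string with unit
#'   suffix (\code{"1.5nm"}, \code{"15A"}). Default 1.5 nm.
#' @param min_points minimum neighborhood size for a core point. Default 2.
#' @param count_self whether the point itself counts toward
#'   \code{min_points} (default TRUE; then min_points = 2 means "at least
#'   one neighbor", which removes border-point ambiguity entirely for the
#'   default setting). FALSE restores the exclusive convention.
#' @param pbc_mode \code{"minimum-image"} (default; physically correct for
#'   periodic boxes) or \code{"none"} (naive Euclidean, for replication
#'   studies).
#' @return list of class \code{aggtraj_clustering_params}.
#' @export
clustering_params <- function(epsilon = 1.5, min_points = 2,
                              count_self = TRUE,
                              pbc_mode = c("minimum-image", "none")) {
  epsilon <- parse_length_nm(epsilon)
  pbc_mode <- match.arg(pbc_mode)
  if (!is.finite(epsilon) || epsilon <= 0) stop("epsilon must be > 0")
  if (min_points < 1) stop("min_points must be >= 1")
  structure(list(epsilon = epsilon, min_points = as.integer(min_points),
                 count_self = isTRUE(count_self), pbc_mode = pbc_mode),
            class = "aggtraj_clustering_params")
}

# Union-find with path compression; used for core-core merging.
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Partition molecular COMs into aggregates (DBSCAN)
#'
#' Core points are those with at least \code{min_points} neighbors within
#' \code{epsilon} (self-inclusive by default). Core points connected within
#' epsilon are merged; a non-core point with a core neighbor (a border
#' point) joins the cluster of its nearest core neighbor, distance ties
#' resolved toward the lower canonical aggregate. Everything else is free
#' (noise). Aggregates are canonicalized -- sorted by size descending, then
#' by smallest member id -- so the output is independent of input order.
#'
#' With the default \code{min_points = 2} every clustered point is core and
#' the partition equals the connected components of the graph joining COMs
#' within epsilon.
#'
#' @param coms an \code{aggtraj_comset}. The comset's own \code{pbc_mode} is
#'   overridden by \code{params$pbc_mode}.
#' @param params \code{\link{clustering_params}}.
#' @param topo topology (for species composition of each aggregate).
#' @return object of class \code{aggtraj_aggregates}: list with
#'   \code{$aggregates} (list of ascending molecule-id vectors),
#'   \code{$noise} (ascending molecule ids), \code{$composition} (data.frame
#'   aggregate x species counts), \code{$frame}, \code{$time},
#'   \code{$params}, \code{$n_molecules}.
#' @export
dbscan_aggregates <- function(coms, params = clustering_params(),
                              topo = NULL) {
  stopifnot(inherits(coms, "aggtraj_comset"))
  pts <- coms$points
  if (any(!is.finite(pts))) stop("non-finite center of mass")
  n <- nrow(pts)
  mols <- coms$molecules
  eps <- params$epsilon

  labels <- integer(n)  # 0 = noise
  if (n >= 2) {
    d <- pairwise_distances(pts, coms$box, params$pbc_mode)
    adj <- d <= eps
    diag(adj) <- FALSE
    ncount <- rowSums(adj) + if (params$count_self) 1L else 0L
    core <- ncount >= params$min_points
    parent <- seq_len(n)
    for (i in which(core)) {
      for (j in which(adj[i, ] & core)) {
        ri <- uf_find(parent, i); rj <- uf_find(parent, j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
    roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
    labels[core] <- match(roots[core], sort(unique(roots[core])))
    # deterministic border assignment: nearest core neighbor; distance ties
    # -> lower canonical aggregate (resolved below after canonical order)
    border <- which(!core & (adj %*% core > 0))
    border_choices <- lapply(border, function(i) {
      cand <- which(adj[i, ] & core)
      dmin <- min(d[i, cand])
      unique(labels[cand[d[i, cand] <= dmin]])
    })
  } else if (n == 1) {
    core <- params$min_points <= (if (params$count_self) 1L else 0L)
    if (core) labels[1] <- 1L
    border <- integer(0); border_choices <- list()
  } else {
    border <- integer(0); border_choices <- list()
  }

  # canonical order of core clusters by (size desc, smallest member id)
  ids <- sort(unique(labels[labels > 0]))
  groups <- lapply(ids, function(k) sort(mols[labels == k]))
  ord <- order(-vapply(groups, length, integer(1)),
               vapply(groups, min, numeric(1)))
  groups <- groups[ord]
  canon_of <- integer(max(c(ids, 0L)))
  canon_of[ids[ord]] <- seq_along(ord)
  # attach borders to the lowest canonical aggregate among nearest cores
  if (length(border)) {
    for (t in seq_along(border)) {
      tgt <- min(canon_of[border_choices[[t]]])
      groups[[tgt]] <- sort(c(groups[[tgt]], mols[border[t]]))
      labels[border[t]] <- -1L  # mark as clustered
    }
    # re-canonicalize: border additions can change sizes
    ord2 <- order(-vapply(groups, length, integer(1)),
                  vapply(groups, min, numeric(1)))
    groups <- groups[ord2]
  }
  noise <- sort(mols[labels == 0L])

  comp <- NULL
  if (!is.null(topo)) {
    comp <- do.call(rbind, lapply(groups, function(g) composition(g, topo)))
    if (is.null(comp)) {
      comp <- composition(integer(0), topo)[0, , drop = FALSE]
    }
  }
  structure(list(aggregates = groups, noise = noise, composition = comp,
                 frame = coms$frame, time = coms$time,
                 n_molecules = n, params = params),
            class = "aggtraj_aggregates")
}

#' @export
print.aggtraj_aggregates <- function(x, ...) {
  sizes <- vapply(x$aggregates, length, integer(1))
  cat("Frame", x$frame, "aggregates:", length(sizes),
      if (length(sizes)) paste0("(sizes ", paste(sizes, collapse = ", "), ")")
      else "", "+", length(x$noise), "free molecules\n")
  invisible(x)
}

#' Species composition of a molecule set
#'
#' @param molecules integer molecule ids (an aggregate's members; may be
#'   empty).
#' @param topo topology whose registry defines the solute species and the
#'   column order.
#' @return one-row data.frame of per-species molecule counts summing to the
#'   set size.
#' @export
composition <- function(molecules, topo) {
  tags <- solute_species_tags(topo)
  sp <- molecule_species(topo)
  cnt <- vapply(tags, function(tg) {
    sum(sp[as.character(molecules)] == tg)
  }, integer(1))
  as.data.frame(as.list(cnt), optional = TRUE)
}

#' Rand index between two partitions of the same molecules
#'
#' Used to score recovered aggregate partitions against planted ground
#' truth. Free molecules are treated as singleton clusters.
#'
#' @param labels_a,labels_b integer label vectors over the same molecules;
#'   0 means free and is expanded to a unique singleton label.
#' @return Rand index in [0, 1]; 1 iff the partitions are identical.
#' @export
rand_index <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b))
  expand <- function(l) {
    l <- as.integer(l)
    free <- l == 0L
    if (any(free)) l[free] <- max(l) + seq_len(sum(free))
    l
  }
  a <- expand(labels_a); b <- expand(labels_b)
  n <- length(a)
  if (n < 2) return(1)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  up <- upper.tri(same_a)
  mean(same_a[up] == same_b[up])
}

# Integer labels (0 = free) for an aggregate set over given molecule ids,
# in canonical aggregate order.
aggregate_labels <- function(aggs, molecules) {
  lab <- stats::setNames(integer(length(molecules)), molecules)
  for (k in seq_along(aggs$aggregates)) {
    lab[as.character(aggs$aggregates[[k]])] <- k
  }
  unname(lab)
}
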