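# Shared builders and independent oracles for the test suite.

# Single-particle two-species topology: molecules 1..n1 are CM15,
# n1+1..n1+n2 are SUR; optionally n_lip single-particle lipids carrying the
# phosphorus-reference role.
make_topo <- function(n1 = 2, n2 = 2, n_lip = 0, lipid_tag = "DOPC") {
  n <- n1 + n2 + n_lip
  topology(
    particle = seq_len(n),
    molecule = seq_len(n),
    species = c(rep("CM15", n1), rep("SUR", n2), rep(lipid_tag, n_lip)),
    role = c(rep("regular", n1 + n2), rep("phosphorus-reference", n_lip))
  )
}

make_frame <- function(coords, box = c(10, 10, 10), index = 1, time = 0) {
  frame(index, time, box, matrix(coords, ncol = 3, byrow = TRUE))
}

# comset constructed directly from molecule COM points (bypasses per-frame
# COM computation; used to feed clustering with exact positions)
make_comset <- function(points, box = c(10, 10, 10), molecules = NULL,
                        pbc_mode = "minimum-image", frame = 1, time = 0) {
  points <- matrix(points, ncol = 3, byrow = TRUE)
  if (is.null(molecules)) molecules <- seq_len(nrow(points))
  structure(list(points = points, molecules = as.integer(molecules),
                 frame = frame, time = time, box = box,
                 pbc_mode = pbc_mode, weighting = "geometric"),
            class = "aggtraj_comset")
}

# AggregateSet built directly from a partition (canonical order applied),
# for metric tests that do not involve clustering.
make_aggset <- function(groups, noise = integer(0), frame = 1, time = 0,
                        topo = NULL) {
  groups <- lapply(groups, function(g) sort(as.integer(g)))
  ord <- order(-vapply(groups, length, integer(1)),
               vapply(groups, function(g) min(c(g, Inf)), numeric(1)))
  groups <- groups[ord]
  n <- sum(vapply(groups, length, integer(1))) + length(noise)
  comp <- if (!is.null(topo)) {
    do.call(rbind, lapply(groups, function(g) composition(g, topo)))
  } else NULL
  structure(list(aggregates = groups, noise = sort(as.integer(noise)),
                 composition = comp, frame = frame, time = time,
                 n_molecules = n, params = clustering_params()),
            class = "aggtraj_aggregates")
}

# Independent clustering oracle: connected components of the epsilon-graph
# via igraph, as sorted member sets in canonical order.
oracle_components <- function(points, box, eps,
                              pbc_mode = "minimum-image",
                              molecules = NULL) {
  points <- matrix(points, ncol = 3, byrow = FALSE)
  if (is.null(molecules)) molecules <- seq_len(nrow(points))
  d <- aggtraj:::pairwise_distances(points, box, pbc_mode)
  adj <- d <= eps
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  mem <- igraph::components(g)$membership
  groups <- lapply(split(molecules, mem), function(g) sort(as.integer(g)))
  keep <- vapply(groups, length, integer(1)) >= 2
  noise <- sort(as.integer(unlist(groups[!keep])))
  groups <- unname(groups[keep])
  ord <- order(-vapply(groups, length, integer(1)),
               vapply(groups, function(g) min(c(g, Inf)), numeric(1)))
  list(aggregates = groups[ord], noise = noise)
}

# comparable canonical form of an AggregateSet
partition_of <- function(aggs) {
  list(aggregates = aggs$aggregates, noise = aggs$noise)
}
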