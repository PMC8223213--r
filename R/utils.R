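#' @keywords internal
"_PACKAGE"

# column names used in non-standard evaluation (ggplot2 aes)
utils::globalVariables(c("time_ns", "complex_ratio",
                         "avg_aggregation_number", "contacts", "species",
                         "count"))

# Periodic-boundary helpers. All lengths are nm; boxes are orthorhombic
# (edge lengths only), enforced at the I/O boundary.

#' Wrap coordinates into the primary box
#'
#' @param x numeric matrix (n x 3) or length-3 vector of positions, nm.
#' @param box length-3 numeric, orthorhombic box edge lengths, nm.
#' @return positions wrapped into [0, box) per dimension.
#' @keywords internal
wrap_coords <- function(x, box) {
  if (is.null(dim(x))) {
    x - floor(x / box) * box
  } else {
    x - sweep(floor(sweep(x, 2, box, "/")), 2, box, "*")
  }
}

# Minimum-image displacement: d may be a vector or matrix of raw
# displacements; returns the nearest-periodic-copy displacement.
min_image <- function(d, box) {
  if (is.null(dim(d))) {
    d - round(d / box) * box
  } else {
    d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
  }
}

# Pairwise Euclidean distance matrix for points (n x 3), optionally under
# the minimum-image convention.  n is at most a few hundred molecules in
# practice, so the dense O(n^2) form is fine.
pairwise_distances <- function(points, box = NULL,
                               pbc_mode = c("minimum-image", "none")) {
  pbc_mode <- match.arg(pbc_mode)
  n <- nrow(points)
  d2 <- matrix(0, n, n)
  for (k in seq_len(ncol(points))) {
    dk <- outer(points[, k], points[, k], "-")
    if (pbc_mode == "minimum-image") dk <- dk - round(dk / box[k]) * box[k]
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}

# Distances from each row of a to each row of b (m x n), min-image optional.
cross_distances <- function(a, b, box = NULL,
                            pbc_mode = c("minimum-image", "none")) {
  pbc_mode <- match.arg(pbc_mode)
  d2 <- matrix(0, nrow(a), nrow(b))
  for (k in seq_len(ncol(a))) {
    dk <- outer(a[, k], b[, k], "-")
    if (pbc_mode == "minimum-image") dk <- dk - round(dk / box[k]) * box[k]
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}

# Shortest decimal representation that reparses to the exact double.
# Used for all CSV/JSON output so that repeated runs are byte-identical
# while keeping full precision.
format_full <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    v <- x[i]
    if (is.na(v)) { out[i] <- "NA"; next }
    s <- sprintf("%.15g", v)
    if (as.numeric(s) != v) s <- sprintf("%.16g", v)
    if (as.numeric(s) != v) s <- sprintf("%.17g", v)
    out[i] <- s
  }
  out
}

# Deterministic RNG scope: fixes the generator kind so the same seed gives
# the same stream across R versions, and restores the caller's RNG state.
with_rng <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

# Parse a length with unit suffix ("1.5nm", "15A", plain number = nm).
parse_length_nm <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(x)
  if (grepl("nm$", x, ignore.case = TRUE)) {
    as.numeric(sub("nm$", "", x, ignore.case = TRUE))
  } else if (grepl("(A|Å|ang|angstrom)$", x, ignore.case = TRUE)) {
    as.numeric(sub("(A|Å|ang|angstrom)$", "", x, ignore.case = TRUE)) / 10
  } else {
    as.numeric(x)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
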