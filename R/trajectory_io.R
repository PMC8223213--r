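# Readers for standard MD structure formats (GRO, PDB; single- or
# multi-frame), the package's native plain-text fixture format, and the
# metric/composition/lineage writers. Internal unit is nm; PDB Angstroms
# are converted at this boundary. Orthorhombic boxes only: triclinic input
# is refused rather than silently mis-wrapped.

FIXTURE_MAGIC <- "#aggtraj-fixture 1"

# ---- GRO ------------------------------------------------------------------

parse_gro_frames <- function(lines, path) {
  frames <- list()
  atoms <- NULL
  i <- 1; fidx <- 0
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    title <- lines[i]
    if (i + 1 > length(lines)) stop("truncated GRO file: ", path)
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1])))
    if (is.na(nat)) stop("bad atom count at line ", i + 1, " of ", path)
    if (i + 1 + nat + 1 > length(lines)) {
      stop("truncated GRO frame starting at line ", i, " of ", path)
    }
    at <- lines[(i + 2):(i + 1 + nat)]
    resid <- as.integer(substr(at, 1, 5))
    resname <- trimws(substr(at, 6, 10))
    atomname <- trimws(substr(at, 11, 15))
    xyz <- cbind(as.numeric(substr(at, 21, 28)),
                 as.numeric(substr(at, 29, 36)),
                 as.numeric(substr(at, 37, 44)))
    if (any(is.na(xyz)) || any(is.na(resid))) {
      stop("malformed GRO atom record in frame starting at line ", i,
           " of ", path)
    }
    boxv <- as.numeric(strsplit(trimws(lines[i + 1 + nat + 1]),
                                "\\s+")[[1]])
    if (length(boxv) == 9) {
      if (any(abs(boxv[4:9]) > 1e-9)) {
        stop("triclinic box in ", path, "; only orthorhombic boxes are ",
             "supported")
      }
      boxv <- boxv[1:3]
    }
    if (length(boxv) != 3) stop("bad GRO box line in ", path)
    fidx <- fidx + 1
    tm <- fidx - 1  # overridden below if the title carries t=
    m <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    if (length(m)) tm <- as.numeric(sub("t=\\s*", "", m)) / 1000  # ps -> ns
    frames[[fidx]] <- list(time = tm, box = boxv, coords = xyz,
                           resid = resid, resname = resname,
                           atomname = atomname,
                           chain = rep("A", nat))
    i <- i + 1 + nat + 2
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1
  }
  if (!length(frames)) stop("no frames in GRO file: ", path)
  frames
}

# ---- PDB ------------------------------------------------------------------

parse_pdb_frames <- function(lines, path) {
  box <- NULL
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (length(cr)) {
    a <- as.numeric(substr(cr[1], 7, 15))
    b <- as.numeric(substr(cr[1], 16, 24))
    c3 <- as.numeric(substr(cr[1], 25, 33))
    ang <- c(as.numeric(substr(cr[1], 34, 40)),
             as.numeric(substr(cr[1], 41, 47)),
             as.numeric(substr(cr[1], 48, 54)))
    if (any(abs(ang - 90) > 1e-6)) {
      stop("triclinic box in ", path, "; only orthorhombic boxes are ",
           "supported")
    }
    box <- c(a, b, c3) / 10  # A -> nm
  }
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  frames <- list()
  slice_atoms <- function(sel) {
    at <- lines[sel]
    xyz <- cbind(as.numeric(substr(at, 31, 38)),
                 as.numeric(substr(at, 39, 46)),
                 as.numeric(substr(at, 47, 54))) / 10  # A -> nm
    if (any(is.na(xyz))) stop("malformed PDB coordinates in ", path)
    list(coords = xyz,
         resid = as.integer(substr(at, 23, 26)),
         resname = trimws(substr(at, 18, 21)),
         atomname = trimws(substr(at, 13, 16)),
         chain = substr(at, 22, 22))
  }
  if (!length(model_starts)) {
    sel <- which(is_atom)
    if (!length(sel)) stop("no ATOM records in ", path)
    frames[[1]] <- c(slice_atoms(sel), list(time = 0, box = box))
  } else {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) < length(model_starts)) {
      stop("PDB MODEL without ENDMDL in ", path)
    }
    for (k in seq_along(model_starts)) {
      sel <- which(is_atom & seq_along(lines) > model_starts[k] &
                     seq_along(lines) < ends[k])
      if (!length(sel)) stop("empty MODEL ", k, " in ", path)
      frames[[k]] <- c(slice_atoms(sel), list(time = k - 1, box = box))
    }
  }
  frames
}

# ---- topology from parsed atoms ------------------------------------------

# Molecule identity is (chain, residue number); species whose tag appears in
# merge_species have consecutive same-tag residues within one chain merged
# into a single molecule (multi-residue ligands).
build_topology <- function(fr0, species_map, merge_species = character(0),
                           role_rules = list(
                             "phosphorus-reference" = c("P", "PO4", "P8")),
                           masses = NULL) {
  resname <- fr0$resname
  unknown <- setdiff(unique(resname), names(species_map))
  if (length(unknown)) {
    stop("no species_map rule for residue name(s): ",
         paste(unknown, collapse = ", "))
  }
  sp <- unname(species_map[resname])
  key <- paste(fr0$chain, fr0$resid, sep = "/")
  newres <- !duplicated(key)
  # sequential residue index in file order
  res_seq <- cumsum(newres)
  res_tag <- sp[newres]
  # merge consecutive residues of a merge species into one molecule
  mol_of_res <- integer(length(res_tag))
  cur <- 0L
  for (r in seq_along(res_tag)) {
    if (r > 1 && res_tag[r] %in% merge_species &&
          res_tag[r] == res_tag[r - 1]) {
      mol_of_res[r] <- cur
    } else {
      cur <- cur + 1L
      mol_of_res[r] <- cur
    }
  }
  molecule <- mol_of_res[res_seq]
  role <- rep("regular", length(resname))
  for (rl in names(role_rules)) {
    role[fr0$atomname %in% role_rules[[rl]]] <- rl
  }
  mass <- rep(1, length(resname))
  if (!is.null(masses)) {
    hit <- fr0$atomname %in% names(masses)
    mass[hit] <- unname(masses[fr0$atomname[hit]])
  }
  topology(particle = seq_along(resname), molecule = molecule,
           species = sp, mass = mass, role = role)
}

#' Load an MD trajectory from standard formats
#'
#' Reads a GRO or PDB structure file and, optionally, a separate
#' multi-frame coordinate file (multi-frame GRO or PDB). Every residue name
#' must be covered by \code{species_map}; binary trajectory formats
#' (XTC/TRR) are not supported and raise an informative error.
#'
#' @param structure_path GRO or PDB file defining particles and topology.
#' @param coords_path optional multi-frame GRO/PDB supplying the frames;
#'   when absent the structure file's own frame(s) are used.
#' @param species_map named character vector: residue name -> species tag.
#' @param merge_species species tags whose consecutive residues within a
#'   chain are merged into one molecule (multi-residue ligands).
#' @param role_rules named list: role flag -> atom names carrying it.
#' @param masses optional named numeric vector: atom name -> mass (amu);
#'   unlisted atoms get mass 1.
#' @param dt frame spacing in ns used when the file carries no time stamps.
#' @return an \code{aggtraj_bundle} without ground truth.
#' @export
load_trajectory <- function(structure_path, coords_path = NULL, species_map,
                            merge_species = character(0),
                            role_rules = list(
                              "phosphorus-reference" = c("P", "PO4", "P8")),
                            masses = NULL, dt = 1) {
  read_any <- function(path) {
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("xtc", "trr")) {
      stop("binary trajectory format '", ext, "' is not supported; ",
           "convert to multi-frame GRO/PDB (e.g. gmx trjconv) or use the ",
           "native fixture format")
    }
    lines <- readLines(path, warn = FALSE)
    if (ext == "gro") parse_gro_frames(lines, path)
    else if (ext %in% c("pdb", "ent")) parse_pdb_frames(lines, path)
    else stop("unsupported structure format: ", ext)
  }
  sframes <- read_any(structure_path)
  fr0 <- sframes[[1]]
  topo <- build_topology(fr0, species_map, merge_species, role_rules, masses)
  cframes <- if (is.null(coords_path)) sframes else read_any(coords_path)
  np <- nrow(topo$particles)
  out <- vector("list", length(cframes))
  for (k in seq_along(cframes)) {
    cf <- cframes[[k]]
    if (nrow(cf$coords) != np) {
      stop("particle-count mismatch: structure has ", np,
           " particles but coordinate frame ", k, " has ", nrow(cf$coords))
    }
    bx <- cf$box %||% fr0$box
    if (is.null(bx)) stop("no box information in input files")
    tm <- if (!is.null(cf$time) && length(cframes) > 1 &&
                any(vapply(cframes, `[[`, numeric(1), "time") != 0)) {
      cf$time
    } else (k - 1) * dt
    out[[k]] <- frame(k, tm, bx, cf$coords)
  }
  bundle(out, topo)
}

# ---- native fixture format -----------------------------------------------

#' Write a bundle in the native fixture format
#'
#' A one-line JSON header (species registry, particle table, box mode,
#' metadata) followed by one plain-text block per frame: a
#' \code{#frame <index> <time_ns> <bx> <by> <bz>} line and one
#' \code{x y z} line per particle (nm, 6 decimals). When the bundle carries
#' ground truth a JSON sidecar \code{<path>.truth.json} is written with the
#' per-frame label arrays and the scripted event log. Coordinates are
#' expected on the 1e-6 nm grid the format stores, so write followed by
#' load is the identity.
#'
#' @param bun an \code{aggtraj_bundle}.
#' @param path output file path.
#' @return path, invisibly.
#' @export
write_fixture <- function(bun, path) {
  stopifnot(inherits(bun, "aggtraj_bundle"))
  topo <- bun$topology
  sp <- topo$species; rownames(sp) <- NULL
  pt <- topo$particles; rownames(pt) <- NULL
  header <- list(
    species = sp,
    particles = pt,
    box_mode = "orthorhombic",
    meta = bun$meta
  )
  con <- file(path, open = "wb")  # binary: LF line endings everywhere
  on.exit(close(con))
  wl <- function(x) writeLines(x, con, sep = "\n")
  wl(FIXTURE_MAGIC)
  wl(jsonlite::toJSON(header, dataframe = "columns", auto_unbox = TRUE,
                      digits = NA))
  for (fr in bun$frames) {
    wl(sprintf("#frame %d %.6f %.6f %.6f %.6f", fr$index, fr$time,
               fr$box[1], fr$box[2], fr$box[3]))
    wl(sprintf("%.6f %.6f %.6f", fr$coords[, 1], fr$coords[, 2],
               fr$coords[, 3]))
  }
  if (!is.null(bun$ground_truth)) {
    gt <- bun$ground_truth
    jsonlite::write_json(
      list(molecules = as.integer(gt$molecules),
           labels = lapply(gt$labels, as.integer),
           events = gt$events),
      paste0(path, ".truth.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(path)
}

#' Load a native fixture file
#'
#' Reattaches the ground-truth sidecar \code{<path>.truth.json} when it
#' exists. Malformed headers or frame blocks raise errors naming the line;
#' a truncated final frame is an error, never a silent drop.
#'
#' @param path fixture file written by \code{\link{write_fixture}}.
#' @return an \code{aggtraj_bundle}.
#' @export
load_fixture <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || lines[1] != FIXTURE_MAGIC) {
    stop("not a native fixture file (bad magic at line 1): ", path)
  }
  if (length(lines) < 2) stop("missing fixture header at line 2: ", path)
  header <- tryCatch(jsonlite::fromJSON(lines[2]),
                     error = function(e) {
                       stop("malformed fixture header at line 2 of ", path,
                            ": ", conditionMessage(e))
                     })
  pt <- as.data.frame(header$particles, stringsAsFactors = FALSE)
  topo <- topology(pt$particle, pt$molecule, pt$species, pt$mass, pt$role,
                   registry = as.data.frame(header$species,
                                            stringsAsFactors = FALSE))
  np <- nrow(pt)
  frames <- list()
  i <- 3
  while (i <= length(lines)) {
    if (!startsWith(lines[i], "#frame ")) {
      stop("expected '#frame' at line ", i, " of ", path)
    }
    hd <- as.numeric(strsplit(sub("^#frame ", "", lines[i]), " ")[[1]])
    if (length(hd) != 5 || any(is.na(hd))) {
      stop("malformed frame header at line ", i, " of ", path)
    }
    if (i + np > length(lines)) {
      stop("truncated frame block at line ", i, " of ", path,
           " (expected ", np, " coordinate lines)")
    }
    block <- lines[(i + 1):(i + np)]
    xyz <- matrix(as.numeric(unlist(strsplit(block, " ", fixed = TRUE))),
                  ncol = 3, byrow = TRUE)
    if (any(is.na(xyz))) {
      stop("malformed coordinate line near line ", i + 1, " of ", path)
    }
    frames[[length(frames) + 1]] <- frame(hd[1], hd[2], hd[3:5], xyz)
    i <- i + np + 1
  }
  if (!length(frames)) stop("fixture has no frames: ", path)
  gt <- NULL
  sidecar <- paste0(path, ".truth.json")
  if (file.exists(sidecar)) {
    raw <- jsonlite::fromJSON(sidecar, simplifyDataFrame = TRUE,
                              simplifyMatrix = FALSE)
    gt <- list(molecules = as.integer(raw$molecules),
               labels = lapply(raw$labels, as.integer),
               events = as.data.frame(raw$events,
                                      stringsAsFactors = FALSE))
  }
  bundle(frames, topo, ground_truth = gt,
         meta = if (is.null(header$meta)) list() else header$meta)
}

# ---- tabular writers ------------------------------------------------------

#' Write a metric time series (or any data.frame) as CSV
#'
#' One row per frame, stable column order, full float precision (shortest
#' decimal that reparses to the exact double), LF line endings: repeated
#' writes of the same series are byte-identical.
#'
#' @param table data.frame, e.g. from \code{\link{metric_time_series}}.
#' @param path output path.
#' @return path, invisibly.
#' @export
write_metrics <- function(table, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(table), collapse = ","), con, sep = "\n")
  if (nrow(table)) {
    cols <- lapply(table, function(col) {
      if (is.numeric(col)) format_full(col) else as.character(col)
    })
    writeLines(do.call(paste, c(cols, sep = ",")), con, sep = "\n")
  }
  invisible(path)
}

#' Write a composition table as CSV
#'
#' Columns: time_ns, then the per-species class counts, then count.
#'
#' @param tab an \code{aggtraj_composition_table} (or several rbind-ed).
#' @param path output path.
#' @return path, invisibly.
#' @export
write_composition_csv <- function(tab, path) {
  ncols <- grep("^n_", names(tab), value = TRUE)
  out <- as.data.frame(tab)[, c("time_ns", ncols, "count")]
  write_metrics(out, path)
}

#' Export frame 0 of a bundle as a GRO file
#'
#' Interoperability helper: writes the first frame in GROMACS GRO format
#' (nm, 3 decimals) so fixtures can be inspected in standard tools.
#'
#' @param bun an \code{aggtraj_bundle}.
#' @param path output path.
#' @return path, invisibly.
#' @export
write_gro <- function(bun, path) {
  fr <- bun$frames[[1]]
  p <- bun$topology$particles
  con <- file(path, open = "wb")
  on.exit(close(con))
  wl <- function(x) writeLines(x, con, sep = "\n")
  wl(sprintf("aggtraj fixture frame %d, t= %.3f", fr$index, fr$time * 1000))
  wl(sprintf("%5d", nrow(p)))
  nm <- substr(p$species, 1, 5)
  an <- ifelse(p$role == "phosphorus-reference", "P",
               substr(paste0("B", seq_len(nrow(p))), 1, 5))
  wl(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
             p$molecule %% 100000, nm, an, p$particle %% 100000,
             fr$coords[, 1], fr$coords[, 2], fr$coords[, 3]))
  wl(sprintf("%10.5f%10.5f%10.5f", fr$box[1], fr$box[2], fr$box[3]))
  invisible(path)
}
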