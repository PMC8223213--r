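#' Molecule topology: particle-to-molecule grouping and species registry
#'
#' A topology maps every particle to exactly one molecule and every molecule
#' to exactly one species (e.g. CM15, SUR, DOPC, DOPG). Particles carry a
#' mass (amu; defaults to 1 for coarse-grained/fixture input) and a role
#' flag. The role \code{"phosphorus-reference"} marks the particle whose z
#' position defines the lipid's leaflet; lipids are exactly the molecules
#' whose species contains such a particle (or whose species is registered
#' with \code{solute = FALSE}).
#'
#' @param particle integer particle ids (unique).
#' @param molecule integer molecule ids.
#' @param species character species tag per particle (constant within a
#'   molecule).
#' @param mass numeric particle masses, amu; all > 0.
#' @param role one of \code{"regular"}, \code{"phosphorus-reference"},
#'   \code{"headgroup"}, \code{"none"} per particle.
#' @param registry optional data.frame with columns \code{tag}, \code{name},
#'   \code{solute}; autogenerated if omitted (species with any
#'   phosphorus-reference particle are treated as lipids).
#' @return an object of class \code{aggtraj_topology}: a list with
#'   \code{$particles} (data.frame) and \code{$species} (registry).
#' @export
topology <- function(particle, molecule, species,
                     mass = rep(1, length(particle)),
                     role = rep("regular", length(particle)),
                     registry = NULL) {
  n <- length(particle)
  stopifnot(length(molecule) == n, length(species) == n,
            length(mass) == n, length(role) == n)
  if (anyDuplicated(particle)) stop("duplicate particle ids")
  if (any(!is.finite(mass)) || any(mass <= 0)) {
    stop("particle masses must be finite and > 0")
  }
  ok_roles <- c("regular", "phosphorus-reference", "headgroup", "none")
  if (!all(role %in% ok_roles)) {
    stop("unknown role flag; allowed: ", paste(ok_roles, collapse = ", "))
  }
  # one species per molecule
  sp_per_mol <- tapply(species, molecule, function(s) length(unique(s)))
  if (any(sp_per_mol > 1)) {
    bad <- names(sp_per_mol)[sp_per_mol > 1][1]
    stop("molecule ", bad, " has more than one species tag")
  }
  particles <- data.frame(
    particle = as.integer(particle), molecule = as.integer(molecule),
    species = as.character(species), mass = as.numeric(mass),
    role = as.character(role), stringsAsFactors = FALSE
  )
  if (is.null(registry)) {
    tags <- unique(particles$species)
    has_p <- vapply(tags, function(tg) {
      any(particles$role[particles$species == tg] == "phosphorus-reference")
    }, logical(1))
    registry <- data.frame(tag = tags, name = tags, solute = unname(!has_p),
                           stringsAsFactors = FALSE)
  } else {
    registry <- as.data.frame(registry, stringsAsFactors = FALSE)
    stopifnot(all(c("tag", "solute") %in% names(registry)))
    if (is.null(registry$name)) registry$name <- registry$tag
    missing <- setdiff(unique(particles$species), registry$tag)
    if (length(missing)) {
      stop("species in particle table missing from registry: ",
           paste(missing, collapse = ", "))
    }
  }
  structure(list(particles = particles, species = registry),
            class = "aggtraj_topology")
}

#' @export
print.aggtraj_topology <- function(x, ...) {
  p <- x$particles
  cat("Molecule topology:", nrow(p), "particles,",
      length(unique(p$molecule)), "molecules,",
      nrow(x$species), "species\n")
  for (i in seq_len(nrow(x$species))) {
    tg <- x$species$tag[i]
    nm <- length(unique(p$molecule[p$species == tg]))
    cat(sprintf("  %s (%s): %d molecules, %s\n", tg, x$species$name[i], nm,
                if (x$species$solute[i]) "solute" else "lipid"))
  }
  invisible(x)
}

# Molecule ids of solute species, in ascending order.
solute_molecules <- function(topo) {
  tags <- topo$species$tag[topo$species$solute]
  sort(unique(topo$particles$molecule[topo$particles$species %in% tags]))
}

# Molecule ids of lipid (non-solute) species.
lipid_molecules <- function(topo) {
  tags <- topo$species$tag[!topo$species$solute]
  sort(unique(topo$particles$molecule[topo$particles$species %in% tags]))
}

# Species tag of each molecule id, named integer-compatible lookup.
molecule_species <- function(topo) {
  p <- topo$particles
  idx <- !duplicated(p$molecule)
  stats::setNames(p$species[idx], p$molecule[idx])
}

# Solute species tags in registry order (stable column order for outputs).
solute_species_tags <- function(topo) {
  topo$species$tag[topo$species$solute]
}

#' Select particle indices by species tag and/or role flag
#'
#' Selections are how config refers to particle groups, e.g. the lipid
#' phosphorus reference is \code{select_particles(topo, role =
#' "phosphorus-reference")}.
#'
#' @param topo an \code{aggtraj_topology}.
#' @param species optional character vector of species tags.
#' @param role optional character vector of role flags.
#' @param molecules optional integer vector of molecule ids.
#' @return integer row indices into the particle table (= coordinate rows).
#' @export
select_particles <- function(topo, species = NULL, role = NULL,
                             molecules = NULL) {
  p <- topo$particles
  keep <- rep(TRUE, nrow(p))
  if (!is.null(species)) keep <- keep & p$species %in% species
  if (!is.null(role)) keep <- keep & p$role %in% role
  if (!is.null(molecules)) keep <- keep & p$molecule %in% molecules
  which(keep)
}
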