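# Synthetic planted-trajectory generator. Aggregation is scripted, not
# simulated: cluster membership follows an explicit event schedule (merge,
# split, dissolve, bind, release), cluster centers perform a bounded random
# walk subject to separation constraints, and members are placed within a
# jitter radius of their center. The generator is ground truth for the
# analyzer, not a physical model; with jitter <= epsilon/4 and center
# separation >= 4*epsilon the planted partition is recovered exactly by the
# default clustering.

#' Specification of a synthetic planted trajectory
#'
#' @param n_species named integer vector, molecules per solute species.
#'   Default \code{c(CM15 = 36, SUR = 36)}, the two-species co-assembly
#'   system size. Molecule ids run 1..sum(n_species) in species order.
#' @param box length-3 box edge lengths, nm.
#' @param n_frames number of frames.
#' @param dt frame spacing, ns (default 10, one frame per 10 ns).
#' @param epsilon clustering radius the spec is built for, nm; used only to
#'   validate the exact-recovery geometry, not by the generator itself.
#' @param jitter cluster member placement radius, nm; keep <= epsilon/4 for
#'   exact recovery. Default 0.3.
#' @param separation minimum distance between cluster centers (and between
#'   a cluster center and a free molecule), nm; >= 4*epsilon for
#'   exact-recovery specs. Default 6.
#' @param free_gap minimum distance between two free molecules, nm; must
#'   exceed epsilon so free molecules stay noise. Default 2*epsilon.
#' @param init_clusters list of integer molecule-id vectors (each >= 2
#'   molecules, pairwise disjoint); everything else starts free.
#' @param events list of scripted events, each a list with \code{frame},
#'   \code{type} in \code{"merge"} (a, b: cluster ids), \code{"split"} (a:
#'   cluster id, members: ids leaving into a new cluster or to freedom if
#'   fewer than 2), \code{"dissolve"} (a: cluster id, all members freed),
#'   \code{"bind"} (molecules: ids moved onto the membrane) or
#'   \code{"release"} (molecules: ids returned to the solution). Events
#'   apply at the start of their frame.
#' @param membrane NULL or a list with \code{z_bottom}, \code{z_top}
#'   (leaflet planes, nm), \code{spacing} (lipid grid spacing, nm),
#'   \code{jitter_xy} (in-plane lipid jitter), \code{bind_spacing} (grid
#'   spacing of binding sites; keep > epsilon so bound monomers stay
#'   noise), \code{species} (lipid species tag).
#' @param particles_per_molecule 1 (default) or 3; with 3 each solute is a
#'   rigid equilateral triad of radius 0.1 nm with random orientation,
#'   exercising the COM/unwrap machinery.
#' @param walk_step random-walk step bound per frame, nm.
#' @param bind_offset z offset of bound molecules above the top leaflet, nm
#'   (default 0.3, inside the default 0.6 nm contact cutoff).
#' @param bind_clearance minimum z clearance of unbound solutes above the
#'   top leaflet, nm (default 2, far outside the contact cutoff).
#' @param seed integer; fixes every random draw.
#' @return list of class \code{aggtraj_synthetic_spec}.
#' @export
synthetic_spec <- function(n_species = c(CM15 = 36, SUR = 36),
                           box = c(25, 25, 25), n_frames = 50, dt = 10,
                           epsilon = 1.5, jitter = 0.3, separation = 6,
                           free_gap = 2 * epsilon,
                           init_clusters = list(), events = list(),
                           membrane = NULL,
                           particles_per_molecule = 1,
                           walk_step = 0.2, bind_offset = 0.3,
                           bind_clearance = 2, seed = 1) {
  stopifnot(length(n_species) >= 1, !is.null(names(n_species)),
            all(n_species >= 1), length(box) == 3, all(box > 0),
            n_frames >= 1, dt > 0, jitter >= 0, separation > 0,
            particles_per_molecule %in% c(1, 3))
  n_total <- sum(n_species)
  all_ids <- seq_len(n_total)
  seen <- integer(0)
  for (cl in init_clusters) {
    if (length(cl) < 2) stop("init_clusters entries need >= 2 molecules")
    if (!all(cl %in% all_ids)) stop("init_clusters references unknown ids")
    if (any(cl %in% seen)) stop("init_clusters must be disjoint")
    seen <- c(seen, cl)
  }
  for (ev in events) {
    if (is.null(ev$frame) || is.null(ev$type) ||
          !ev$type %in% c("merge", "split", "dissolve", "bind", "release")) {
      stop("each event needs a frame and a type in ",
           "merge/split/dissolve/bind/release")
    }
    if (ev$frame < 1 || ev$frame > n_frames) {
      stop("event at frame ", ev$frame, " is outside 1..", n_frames)
    }
    if (ev$type %in% c("bind", "release") && is.null(membrane)) {
      stop("bind/release events require a membrane block")
    }
  }
  if (!is.null(membrane)) {
    defaults <- list(z_bottom = 3, z_top = 5, spacing = 1,
                     jitter_xy = 0.05, bind_spacing = 2, species = "DOPC")
    membrane <- utils::modifyList(defaults, membrane)
    if (membrane$z_top <= membrane$z_bottom) {
      stop("membrane z_top must exceed z_bottom")
    }
    if (membrane$z_top + bind_clearance + 1 >= box[3]) {
      stop("box too small: no solution space above the membrane")
    }
  }
  structure(list(
    n_species = n_species, box = box, n_frames = as.integer(n_frames),
    dt = dt, epsilon = epsilon, jitter = jitter, separation = separation,
    free_gap = free_gap, init_clusters = init_clusters, events = events,
    membrane = membrane,
    particles_per_molecule = as.integer(particles_per_molecule),
    walk_step = walk_step, bind_offset = bind_offset,
    bind_clearance = bind_clearance, seed = as.integer(seed)
  ), class = "aggtraj_synthetic_spec")
}

# sample one point in the allowed region
sample_point <- function(spec, margin_xy, zr) {
  c(stats::runif(1, margin_xy, spec$box[1] - margin_xy),
    stats::runif(1, margin_xy, spec$box[2] - margin_xy),
    stats::runif(1, zr[1], zr[2]))
}

# uniform point in a ball of given radius
ball_jitter <- function(radius) {
  v <- stats::rnorm(3)
  v <- v / sqrt(sum(v^2))
  v * radius * stats::runif(1)^(1 / 3)
}

#' Generate a synthetic trajectory with planted ground truth
#'
#' Replays the scripted event schedule frame by frame, maintaining cluster
#' centers and free-molecule positions on a constraint-respecting bounded
#' random walk, and emits coordinates, per-frame molecule-to-aggregate
#' labels and the event log. Deterministic given the spec's seed; all
#' coordinates are rounded to the 1e-6 nm grid of the native fixture
#' format, so writing and reloading is the identity.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return an \code{aggtraj_bundle} with ground truth.
#' @export
generate_planted_trajectory <- function(spec) {
  stopifnot(inherits(spec, "aggtraj_synthetic_spec"))
  with_rng(spec$seed, generate_planted_impl(spec))
}

#' Generate a membrane-containing synthetic trajectory
#'
#' Convenience entry point for specs with a membrane block (see the
#' \code{"membrane-saturation"} and \code{"membrane-intermediate"} presets):
#' lipids sit on two z-planes with small in-plane jitter and scripted bind
#' events move solutes to within the contact cutoff of the top leaflet.
#'
#' @param spec a \code{\link{synthetic_spec}} with a membrane block.
#' @return an \code{aggtraj_bundle} with ground truth.
#' @export
generate_membrane_trajectory <- function(spec) {
  stopifnot(inherits(spec, "aggtraj_synthetic_spec"))
  if (is.null(spec$membrane)) {
    stop("generate_membrane_trajectory requires a membrane block; ",
         "use generate_planted_trajectory for solution-only specs")
  }
  generate_planted_trajectory(spec)
}

generate_planted_impl <- function(spec) {
  n_total <- sum(spec$n_species)
  tags <- names(spec$n_species)
  mol_species <- rep(tags, spec$n_species)
  box <- spec$box
  mem <- spec$membrane

  # ---- topology -----------------------------------------------------------
  ppm <- spec$particles_per_molecule
  sol_particle_mol <- rep(seq_len(n_total), each = ppm)
  sol_species <- rep(mol_species, each = ppm)
  sol_role <- rep("regular", n_total * ppm)
  lip_xy <- NULL
  if (!is.null(mem)) {
    nx <- floor(box[1] / mem$spacing)
    ny <- floor(box[2] / mem$spacing)
    gx <- (seq_len(nx) - 0.5) * mem$spacing
    gy <- (seq_len(ny) - 0.5) * mem$spacing
    lip_xy <- as.matrix(expand.grid(x = gx, y = gy))
    n_lip_leaf <- nrow(lip_xy)
    lip_mol <- n_total + seq_len(2 * n_lip_leaf)
    lip_species <- rep(mem$species, 2 * n_lip_leaf)
    lip_role <- rep("phosphorus-reference", 2 * n_lip_leaf)
  } else {
    lip_mol <- integer(0); lip_species <- character(0)
    lip_role <- character(0); n_lip_leaf <- 0
  }
  topo <- topology(
    particle = seq_len(n_total * ppm + length(lip_mol)),
    molecule = c(sol_particle_mol, lip_mol),
    species = c(sol_species, lip_species),
    role = c(sol_role, lip_role)
  )

  # ---- scheduling state ---------------------------------------------------
  clusters <- list()  # names = cluster id as character
  next_cluster <- 1L
  for (cl in spec$init_clusters) {
    clusters[[as.character(next_cluster)]] <- sort(as.integer(cl))
    next_cluster <- next_cluster + 1L
  }
  free <- setdiff(seq_len(n_total), unlist(spec$init_clusters))
  bound <- integer(0)          # molecule id -> bind site index (named)
  next_site <- 1L

  # bind sites: top-leaflet grid points thinned to bind_spacing
  bind_sites <- NULL
  if (!is.null(mem)) {
    k <- max(1L, ceiling(mem$bind_spacing / mem$spacing))
    keep_x <- seq(1, floor(box[1] / mem$spacing), by = k)
    keep_y <- seq(1, floor(box[2] / mem$spacing), by = k)
    bind_sites <- as.matrix(expand.grid(
      x = (keep_x - 0.5) * mem$spacing, y = (keep_y - 0.5) * mem$spacing))
  }

  # ---- geometric state ----------------------------------------------------
  zr <- if (!is.null(mem)) {
    c(mem$z_top + spec$bind_clearance, box[3] - 1)
  } else c(1, box[3] - 1)
  margin <- 1
  centers <- list()  # key "c<id>" or "f<mol>" -> xyz

  gap_between <- function(k1, k2) {
    if (startsWith(k1, "f") && startsWith(k2, "f")) spec$free_gap
    else spec$separation
  }
  feasible_at <- function(key, pt, others) {
    for (ok in names(others)) {
      if (ok == key) next
      gap <- gap_between(key, ok)
      d <- min_image(pt - others[[ok]], box)
      if (sqrt(sum(d^2)) < gap) return(FALSE)
    }
    TRUE
  }
  place_entity <- function(key) {
    for (attempt in 1:2000) {
      pt <- sample_point(spec, margin, zr)
      if (feasible_at(key, pt, centers)) return(pt)
    }
    stop("box too small to honor separation constraints while placing ",
         "entity '", key, "' (", length(centers),
         " entities already placed); enlarge the box or reduce the ",
         "entity count")
  }
  drop_entity <- function(key) centers[[key]] <<- NULL
  ensure_entities <- function() {
    # note: paste0("c", character(0)) is "c", not character(0)
    want <- c(if (length(clusters)) paste0("c", names(clusters)),
              if (length(free)) paste0("f", free))
    for (key in setdiff(names(centers), want)) drop_entity(key)
    for (key in setdiff(want, names(centers))) centers[[key]] <<- place_entity(key)
  }

  free_molecule <- function(mols) {
    free <<- sort(c(free, mols))
  }
  unfree_molecule <- function(mols) {
    free <<- setdiff(free, mols)
  }

  # ---- event application --------------------------------------------------
  log_rows <- list()
  log_event <- function(fidx, type, members, cluster = NA, other = NA) {
    log_rows[[length(log_rows) + 1]] <<- data.frame(
      frame = fidx, type = type,
      members = paste(sort(members), collapse = ","),
      cluster = cluster, other = other, stringsAsFactors = FALSE)
  }
  remove_from_cluster <- function(mols) {
    for (id in names(clusters)) {
      rest <- setdiff(clusters[[id]], mols)
      if (length(rest) != length(clusters[[id]])) {
        if (length(rest) >= 2) {
          clusters[[id]] <<- rest
        } else {
          clusters[[id]] <<- NULL
          free_molecule(rest)
        }
      }
    }
  }
  apply_event <- function(ev, fidx) {
    if (ev$type == "merge") {
      a <- as.character(ev$a); b <- as.character(ev$b)
      if (is.null(clusters[[a]]) || is.null(clusters[[b]])) {
        stop("merge event at frame ", fidx, " references missing cluster")
      }
      log_event(fidx, "merge", clusters[[b]], cluster = ev$a, other = ev$b)
      clusters[[a]] <<- sort(c(clusters[[a]], clusters[[b]]))
      clusters[[b]] <<- NULL
    } else if (ev$type == "split") {
      a <- as.character(ev$a)
      if (is.null(clusters[[a]])) {
        stop("split event at frame ", fidx, " references missing cluster")
      }
      members <- sort(as.integer(ev$members))
      if (!all(members %in% clusters[[a]])) {
        stop("split members not in cluster ", a, " at frame ", fidx)
      }
      log_event(fidx, "split", members, cluster = ev$a, other = next_cluster)
      rest <- setdiff(clusters[[a]], members)
      if (length(rest) >= 2) clusters[[a]] <<- rest
      else { clusters[[a]] <<- NULL; free_molecule(rest) }
      if (length(members) >= 2) {
        clusters[[as.character(next_cluster)]] <<- members
        next_cluster <<- next_cluster + 1L
      } else free_molecule(members)
    } else if (ev$type == "dissolve") {
      a <- as.character(ev$a)
      if (is.null(clusters[[a]])) {
        stop("dissolve event at frame ", fidx, " references missing cluster")
      }
      log_event(fidx, "dissolve", clusters[[a]], cluster = ev$a)
      free_molecule(clusters[[a]])
      clusters[[a]] <<- NULL
    } else if (ev$type == "bind") {
      mols <- as.integer(ev$molecules)
      log_event(fidx, "bind", mols)
      unfree_molecule(mols)
      remove_from_cluster(mols)
      for (m in mols) {
        if (next_site > nrow(bind_sites)) {
          stop("out of binding sites at frame ", fidx,
               "; enlarge the box or bind_spacing grid")
        }
        bound[as.character(m)] <<- next_site
        next_site <<- next_site + 1L
      }
    } else if (ev$type == "release") {
      mols <- as.integer(ev$molecules)
      log_event(fidx, "release", mols)
      bound <<- bound[setdiff(names(bound), as.character(mols))]
      free_molecule(mols)
    }
  }

  # ---- main loop ----------------------------------------------------------
  frames <- vector("list", spec$n_frames)
  labels <- vector("list", spec$n_frames)
  np <- nrow(topo$particles)
  ev_frames <- vapply(spec$events, function(e) as.integer(e$frame),
                      integer(1))
  for (fidx in seq_len(spec$n_frames)) {
    for (ev in spec$events[which(ev_frames == fidx)]) apply_event(ev, fidx)
    ensure_entities()
    # bounded random walk, sequential constraint-checked updates
    for (key in sort(names(centers), method = "radix")) {
      prop <- centers[[key]] + stats::runif(3, -spec$walk_step,
                                           spec$walk_step)
      prop[1] <- min(max(prop[1], margin), box[1] - margin)
      prop[2] <- min(max(prop[2], margin), box[2] - margin)
      prop[3] <- min(max(prop[3], zr[1]), zr[2])
      if (feasible_at(key, prop, centers)) centers[[key]] <- prop
    }
    # molecule center positions
    mol_pos <- matrix(NA_real_, n_total, 3)
    lab <- integer(n_total)
    for (id in names(clusters)) {
      ctr <- centers[[paste0("c", id)]]
      for (m in clusters[[id]]) {
        mol_pos[m, ] <- ctr + ball_jitter(spec$jitter)
        lab[m] <- as.integer(id)
      }
    }
    for (m in free) mol_pos[m, ] <- centers[[paste0("f", m)]]
    if (length(bound)) {
      for (m in as.integer(names(bound))) {
        site <- bind_sites[bound[[as.character(m)]], ]
        mol_pos[m, ] <- c(site[1] + stats::runif(1, -0.1, 0.1),
                          site[2] + stats::runif(1, -0.1, 0.1),
                          mem$z_top + spec$bind_offset +
                            stats::runif(1, -0.05, 0.05))
      }
    }
    # particle coordinates
    coords <- matrix(NA_real_, np, 3)
    if (ppm == 1) {
      coords[seq_len(n_total), ] <- mol_pos
    } else {
      r_body <- 0.1
      for (m in seq_len(n_total)) {
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        v <- stats::rnorm(3); v <- v - sum(v * u) * u
        v <- v / sqrt(sum(v^2))
        th <- c(0, 2 * pi / 3, 4 * pi / 3)
        for (k in 1:3) {
          coords[(m - 1) * 3 + k, ] <- mol_pos[m, ] +
            r_body * (cos(th[k]) * u + sin(th[k]) * v)
        }
      }
    }
    if (!is.null(mem)) {
      jit <- function(n) stats::runif(n, -mem$jitter_xy, mem$jitter_xy)
      lip_top <- cbind(lip_xy[, 1] + jit(n_lip_leaf),
                       lip_xy[, 2] + jit(n_lip_leaf), mem$z_top)
      lip_bot <- cbind(lip_xy[, 1] + jit(n_lip_leaf),
                       lip_xy[, 2] + jit(n_lip_leaf), mem$z_bottom)
      coords[(n_total * ppm + 1):np, ] <- rbind(lip_top, lip_bot)
    }
    coords <- round(wrap_coords(coords, box), 6)
    frames[[fidx]] <- frame(fidx, round((fidx - 1) * spec$dt, 6),
                            round(box, 6), coords)
    labels[[fidx]] <- lab
  }
  events_df <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(frame = integer(0), type = character(0),
               members = character(0), cluster = integer(0),
               other = integer(0), stringsAsFactors = FALSE)
  bundle(frames, topo,
         ground_truth = list(labels = labels, events = events_df,
                             molecules = seq_len(n_total)),
         meta = list(generator = "aggtraj planted", seed = spec$seed,
                     n_species = as.list(spec$n_species),
                     jitter = spec$jitter, separation = spec$separation,
                     dt = spec$dt))
}

#' Built-in synthetic scenario presets
#'
#' Four scripted scenarios mirroring the qualitative regimes of a
#' two-species co-assembly study at desk scale:
#' \describe{
#'   \item{\code{"demo"}}{4+4 molecules, two 2:2 clusters merging at frame
#'     5; 12 frames. The packaged end-to-end example.}
#'   \item{\code{"water-aggregation"}}{36+36 molecules in solution; twelve
#'     3:3 clusters fuse pairwise (frames 10, 20, 35, 48) into a single
#'     72-molecule aggregate: complex ratio 1 at the end.}
#'   \item{\code{"membrane-saturation"}}{36+36 over a bilayer slab; an
#'     early 2:2 complex dissolves to monomers while all 36 CM15 bind the
#'     membrane in groups of six by frame 30; suramin stays free.}
#'   \item{\code{"membrane-intermediate"}}{36+36 over a bilayer; 12 CM15
#'     bind while six 3:3 clusters fuse into two aggregates that persist
#'     alongside the contacts.}
#' }
#'
#' @param name preset name.
#' @param seed RNG seed stored in the spec.
#' @return a \code{\link{synthetic_spec}}.
#' @export
synthetic_preset <- function(name = c("demo", "water-aggregation",
                                      "membrane-saturation",
                                      "membrane-intermediate"),
                             seed = 1) {
  name <- match.arg(name)
  if (name == "demo") {
    synthetic_spec(
      n_species = c(CM15 = 4, SUR = 4), box = c(16, 16, 16),
      n_frames = 12, dt = 10,
      init_clusters = list(c(1, 2, 5, 6), c(3, 4, 7, 8)),
      events = list(list(frame = 5, type = "merge", a = 1, b = 2)),
      seed = seed)
  } else if (name == "water-aggregation") {
    init <- lapply(1:12, function(k) {
      c(3 * k - 2:0, 36 + 3 * k - 2:0)
    })
    merge_at <- function(fr, pairs) {
      lapply(pairs, function(p) list(frame = fr, type = "merge",
                                     a = p[1], b = p[2]))
    }
    synthetic_spec(
      n_species = c(CM15 = 36, SUR = 36), box = c(26, 26, 26),
      n_frames = 60, dt = 10, init_clusters = init,
      events = c(
        merge_at(10, list(c(1, 2), c(3, 4), c(5, 6), c(7, 8), c(9, 10),
                          c(11, 12))),
        merge_at(20, list(c(1, 3), c(5, 7), c(9, 11))),
        merge_at(35, list(c(1, 5))),
        merge_at(48, list(c(1, 9)))),
      seed = seed)
  } else if (name == "membrane-saturation") {
    bind_at <- function(fr, mols) list(frame = fr, type = "bind",
                                       molecules = mols)
    synthetic_spec(
      n_species = c(CM15 = 36, SUR = 36), box = c(22, 22, 18),
      n_frames = 50, dt = 10,
      init_clusters = list(c(1, 2, 37, 38)),
      events = list(
        bind_at(5, 3:8),
        list(frame = 8, type = "dissolve", a = 1),
        bind_at(10, c(1, 2, 9:12)),
        bind_at(15, 13:18), bind_at(20, 19:24),
        bind_at(25, 25:30), bind_at(30, 31:36)),
      membrane = list(z_bottom = 3, z_top = 5, spacing = 1,
                      bind_spacing = 2, species = "DOPC"),
      seed = seed)
  } else {
    init <- lapply(1:6, function(k) {
      c(12 + 3 * k - 2:0, 48 + 3 * k - 2:0)
    })
    synthetic_spec(
      n_species = c(CM15 = 36, SUR = 36), box = c(24, 24, 22),
      n_frames = 50, dt = 10, init_clusters = init,
      events = list(
        list(frame = 5, type = "bind", molecules = 1:6),
        list(frame = 10, type = "bind", molecules = 7:12),
        list(frame = 20, type = "merge", a = 1, b = 2),
        list(frame = 20, type = "merge", a = 3, b = 4),
        list(frame = 20, type = "merge", a = 5, b = 6),
        list(frame = 35, type = "merge", a = 1, b = 3)),
      membrane = list(z_bottom = 3, z_top = 5, spacing = 1,
                      bind_spacing = 2, species = "DOPC"),
      seed = seed)
  }
}
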