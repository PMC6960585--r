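#' @useDynLib ringmix, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data abort warn %||%
#' @importFrom stats rnorm
#' @keywords internal
"_PACKAGE"

# Reduced units are fixed globally: k_B T = 1, sigma = 1, m = 1, tau0 = 1.
# No unit-conversion layer exists anywhere in the package.

#' Force-field parameters
#'
#' Interaction constants of the bead-spring model: FENE bonds, the purely
#' repulsive shifted-truncated Lennard-Jones (WCA) pair potential applied to
#' bonded and non-bonded pairs alike, the cosine bending potential (its
#' stiffness lives on the [topology()] chains, not here), and the repulsive
#' wall. All quantities are in reduced units.
#'
#' @param fene_k FENE spring constant (energy/length^2).
#' @param fene_r0 FENE maximum bond extension (length). Must exceed
#'   `lj_sigma`; bonds reaching `fene_r0` are a fatal integration error.
#' @param lj_epsilon WCA repulsion strength between monomers.
#' @param lj_sigma monomer diameter.
#' @param lj_cutoff pair cutoff; the WCA choice `2^(1/6) * lj_sigma` makes the
#'   shifted potential vanish continuously at the cutoff.
#' @param wall_epsilon repulsion strength of the confining wall.
#'
#' @return An object of class `forcefield_params`.
#' @examples
#' ff <- forcefield_params()
#' fene_energy(0.97, ff)
#' @export
forcefield_params <- function(fene_k = 30, fene_r0 = 1.5, lj_epsilon = 1,
                              lj_sigma = 1, lj_cutoff = 2^(1 / 6),
                              wall_epsilon = 1) {
  ff <- structure(
    list(
      fene_k = as.numeric(fene_k), fene_r0 = as.numeric(fene_r0),
      lj_epsilon = as.numeric(lj_epsilon), lj_sigma = as.numeric(lj_sigma),
      lj_cutoff = as.numeric(lj_cutoff), wall_epsilon = as.numeric(wall_epsilon)
    ),
    class = "forcefield_params"
  )
  validate_forcefield_params(ff)
}

validate_forcefield_params <- function(ff) {
  vals <- unlist(ff[c(
    "fene_k", "fene_r0", "lj_epsilon", "lj_sigma",
    "lj_cutoff", "wall_epsilon"
  )])
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all force-field parameters must be positive and finite")
  }
  if (ff$fene_r0 <= ff$lj_sigma) {
    abort(sprintf(
      "fene_r0 (%.3f) must exceed lj_sigma (%.3f)",
      ff$fene_r0, ff$lj_sigma
    ))
  }
  ff
}

#' Chain topology of a polymer mixture
#'
#' A topology is an ordered chain table. Each chain is a ring (bond list
#' closes monomer N back to monomer 1) or a linear chain, with its own length,
#' bending constant and species label. The binary mixtures studied here label
#' chains `"long"` or `"short"`.
#'
#' @param chains a data frame with columns `kind` ("ring" or "linear"),
#'   `n_monomers`, `bending_k`, `species` ("long" or "short").
#' @return An object of class `topology` (a tibble with extra behaviour).
#' @seealso [binary_mixture_topology()] for the standard two-species setup.
#' @export
topology <- function(chains) {
  ch <- tibble::as_tibble(chains)
  req <- c("kind", "n_monomers", "bending_k", "species")
  if (!all(req %in% names(ch))) {
    abort(paste("topology needs columns:", paste(req, collapse = ", ")))
  }
  if (!all(ch$kind %in% c("ring", "linear"))) {
    abort("chain kind must be 'ring' or 'linear'")
  }
  if (!all(ch$species %in% c("long", "short"))) {
    abort("species must be 'long' or 'short'")
  }
  ch$n_monomers <- as.integer(ch$n_monomers)
  if (any(ch$kind == "ring" & ch$n_monomers < 3)) {
    abort("rings need at least 3 monomers")
  }
  if (any(ch$kind == "linear" & ch$n_monomers < 2)) {
    abort("linear chains need at least 2 monomers")
  }
  if (any(ch$bending_k < 0)) abort("bending_k must be non-negative")
  class(ch) <- c("topology", class(tibble::tibble()))
  ch
}

#' Standard binary mixture topology
#'
#' Long chains first, then short chains — the ordering the builder and all
#' species-resolved observables rely on. Long chains may be rings or linear
#' chains (the linear variant is the comparison system); short chains are
#' always rings.
#'
#' @param m_long,n_long number and length of long chains.
#' @param m_short,n_short number and length of short rings.
#' @param kb_long,kb_short bending constants (flexible = 0, stiff >= 50).
#' @param long_kind `"ring"` or `"linear"`.
#' @return A [topology()].
#' @examples
#' top <- binary_mixture_topology(
#'   m_long = 2, n_long = 20, kb_long = 50,
#'   m_short = 10, n_short = 5
#' )
#' @export
binary_mixture_topology <- function(m_long, n_long, kb_long,
                                    m_short, n_short, kb_short = 50,
                                    long_kind = c("ring", "linear")) {
  long_kind <- match.arg(long_kind)
  topology(tibble::tibble(
    kind = c(rep(long_kind, m_long), rep("ring", m_short)),
    n_monomers = c(rep(n_long, m_long), rep(n_short, m_short)),
    bending_k = c(rep(kb_long, m_long), rep(kb_short, m_short)),
    species = c(rep("long", m_long), rep("short", m_short))
  ))
}

#' Confinement geometry
#'
#' Either a hard sphere of radius `R` whose purely repulsive wall acts on the
#' radial gap `R - |r|` (so monomer centres are confined to `|r| <= R - sigma`
#' at thermal energies), or a periodic cubic box used as the bulk reference
#' with no wall at all.
#'
#' The sphere wall comes in two flavours. The default `"smooth"` wall applies
#' the pair potential to the radial gap directly — fast and exactly
#' spherically symmetric. The `"particulate"` wall places explicit
#' wall particles of diameter sigma on a Fibonacci lattice at radius `R`,
#' matching the literal hard-sphere-of-particles construction; observables
#' are insensitive to the choice at the resolutions used here.
#'
#' @param radius sphere radius (length units).
#' @param wall_style `"smooth"` or `"particulate"`.
#' @param edge box edge length.
#' @return An object of class `confinement`.
#' @export
confinement_sphere <- function(radius = 20, wall_style = c("smooth", "particulate")) {
  wall_style <- match.arg(wall_style)
  if (!is.finite(radius) || radius <= 0) abort("sphere radius must be positive")
  conf <- structure(
    list(
      mode = if (wall_style == "smooth") 0L else 1L,
      shape = "sphere", radius = as.numeric(radius), box_edge = NULL,
      wall_style = wall_style, wall_points = NULL
    ),
    class = "confinement"
  )
  if (wall_style == "particulate") {
    conf$wall_points <- fibonacci_sphere_points(radius, spacing = 1)
  }
  conf
}

#' @rdname confinement_sphere
#' @export
confinement_box <- function(edge) {
  if (!is.finite(edge) || edge <= 0) abort("box edge must be positive")
  structure(
    list(
      mode = 2L, shape = "periodic_box", radius = NULL,
      box_edge = as.numeric(edge), wall_style = "none", wall_points = NULL
    ),
    class = "confinement"
  )
}

#' Accessible volume of a confinement
#' @param conf a confinement object.
#' @return Volume in sigma^3 ((4/3) pi R^3 for the sphere, L^3 for the box).
#' @export
confinement_volume <- function(conf) {
  stopifnot(inherits(conf, "confinement"))
  if (conf$shape == "sphere") 4 / 3 * pi * conf$radius^3 else conf$box_edge^3
}

# Near-uniform spherical lattice at ~`spacing` point separation.
fibonacci_sphere_points <- function(radius, spacing = 1) {
  n <- max(12L, ceiling(4 * pi * radius^2 / spacing^2))
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(
    radius * sin(phi) * cos(theta),
    radius * sin(phi) * sin(theta),
    radius * cos(phi)
  )
}

# internal: confinement in the list form the C++ kernels expect
conf_cpp <- function(conf) {
  list(
    mode = conf$mode, radius = conf$radius, box_edge = conf$box_edge,
    wall_points = conf$wall_points
  )
}

#' System state
#'
#' Positions and velocities of every monomer, the topology that maps monomers
#' to chains, and the confinement the system lives in. Monomers are ordered
#' chain by chain in topology order.
#'
#' @param positions,velocities numeric `n x 3` matrices (reduced units).
#' @param topology a [topology()].
#' @param confinement a confinement object.
#' @param time simulation time in tau0.
#' @return An object of class `system_state`.
#' @export
system_state <- function(positions, velocities = NULL, topology, confinement,
                         time = 0) {
  positions <- as.matrix(positions)
  n <- sum(topology$n_monomers)
  if (nrow(positions) != n || ncol(positions) != 3) {
    abort(sprintf("positions must be a %d x 3 matrix for this topology", n))
  }
  if (is.null(velocities)) velocities <- matrix(0, n, 3)
  velocities <- as.matrix(velocities)
  if (!all(dim(velocities) == c(n, 3))) abort("velocities must match positions")
  structure(
    list(
      positions = positions, velocities = velocities, time = time,
      topology = topology, confinement = confinement
    ),
    class = "system_state"
  )
}

#' Check the structural invariants of a system state
#'
#' Verifies finite coordinates, bond lengths below the FENE maximum and (in
#' sphere mode) monomers inside `R - sigma` up to a thermal tolerance.
#'
#' @param state a [system_state()].
#' @param ff force-field parameters.
#' @param tol thermal tolerance on the wall-exclusion radius.
#' @return `state`, invisibly; an error describes the first violation.
#' @export
check_state <- function(state, ff = forcefield_params(), tol = 0.1) {
  stopifnot(inherits(state, "system_state"))
  if (!all(is.finite(state$positions)) || !all(is.finite(state$velocities))) {
    abort("non-finite coordinates in state")
  }
  bl <- bond_lengths(state)
  if (any(bl >= ff$fene_r0)) {
    abort(sprintf(
      "bond length %.4f exceeds FENE maximum %.3f", max(bl), ff$fene_r0
    ))
  }
  if (state$confinement$shape == "sphere") {
    r <- sqrt(rowSums(state$positions^2))
    lim <- state$confinement$radius - ff$lj_sigma + tol
    if (any(r > lim)) {
      abort(sprintf(
        "monomer at |r| = %.4f outside accessible radius %.4f",
        max(r), lim
      ))
    }
  }
  invisible(state)
}

# ---- atom-level derived tables ---------------------------------------------

#' Atom table of a topology
#'
#' One row per monomer with its chain index, species, kind and bending
#' constant — the join table used by species-resolved observables.
#'
#' @param top a [topology()].
#' @return A tibble with columns `atom`, `chain`, `kind`, `species`,
#'   `bending_k`.
#' @export
atom_table <- function(top) {
  tibble::tibble(
    atom = seq_len(sum(top$n_monomers)),
    chain = rep(seq_len(nrow(top)), top$n_monomers),
    kind = rep(top$kind, top$n_monomers),
    species = rep(top$species, top$n_monomers),
    bending_k = rep(top$bending_k, top$n_monomers)
  )
}

# bonds as a 1-based integer matrix; rings close the loop, linear chains don't
bond_list <- function(top) {
  offs <- cumsum(c(0L, top$n_monomers))
  out <- vector("list", nrow(top))
  for (c in seq_len(nrow(top))) {
    n <- top$n_monomers[c]
    i <- offs[c] + seq_len(n - 1)
    b <- cbind(i, i + 1L)
    if (top$kind[c] == "ring") b <- rbind(b, c(offs[c] + n, offs[c] + 1L))
    out[[c]] <- b
  }
  do.call(rbind, out)
}

# angle triplets (i, centre, k) with per-angle bending constant
angle_list <- function(top) {
  offs <- cumsum(c(0L, top$n_monomers))
  trip <- list()
  kvec <- list()
  for (c in seq_len(nrow(top))) {
    n <- top$n_monomers[c]
    if (top$kind[c] == "ring") {
      j <- seq_len(n)
      trip[[c]] <- cbind(
        offs[c] + ifelse(j == 1, n, j - 1L),
        offs[c] + j,
        offs[c] + ifelse(j == n, 1L, j + 1L)
      )
      kvec[[c]] <- rep(top$bending_k[c], n)
    } else if (n >= 3) {
      j <- 2:(n - 1)
      trip[[c]] <- cbind(offs[c] + j - 1L, offs[c] + j, offs[c] + j + 1L)
      kvec[[c]] <- rep(top$bending_k[c], n - 2)
    } else {
      trip[[c]] <- matrix(integer(), 0, 3)
      kvec[[c]] <- numeric()
    }
  }
  list(triplets = do.call(rbind, trip), k = unlist(kvec) %||% numeric())
}

bond_lengths <- function(state) {
  b <- bond_list(state$topology)
  d <- state$positions[b[, 1], , drop = FALSE] -
    state$positions[b[, 2], , drop = FALSE]
  if (state$confinement$shape == "periodic_box") {
    L <- state$confinement$box_edge
    d <- d - L * round(d / L)
  }
  sqrt(rowSums(d^2))
}

# per-chain start index (1-based) and length, for chain-resolved loops
chain_slices <- function(top) {
  offs <- cumsum(c(0L, top$n_monomers))
  tibble::tibble(
    chain = seq_len(nrow(top)),
    start = offs[-length(offs)] + 1L,
    n = top$n_monomers,
    kind = top$kind,
    species = top$species,
    bending_k = top$bending_k
  )
}

# ---- trajectory -------------------------------------------------------------

#' Trajectory container
#'
#' Time-ordered frames at a fixed sampling interval. Coordinates are stored
#' as an `n x 3 x n_frames` array; velocities are optional.
#'
#' @param positions `n x 3 x F` array of frame coordinates.
#' @param times frame times (tau0), strictly increasing, constant spacing.
#' @param topology,confinement as in [system_state()].
#' @param velocities optional `n x 3 x F` array.
#' @param metadata free-form list (resolved config, seed, achieved
#'   temperature...) recorded by [run_md()].
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(positions, times, topology, confinement,
                       velocities = NULL, metadata = list()) {
  stopifnot(length(dim(positions)) == 3, dim(positions)[2] == 3)
  nf <- dim(positions)[3]
  if (length(times) != nf) abort("times must match the number of frames")
  if (nf > 1) {
    dt <- diff(times)
    if (any(dt <= 0) || diff(range(dt)) > 1e-8 * max(dt)) {
      abort("frame times must be strictly increasing with constant spacing")
    }
  }
  structure(
    list(
      positions = positions, velocities = velocities, times = as.numeric(times),
      topology = topology, confinement = confinement,
      sampling_interval = if (nf > 1) times[2] - times[1] else NA_real_,
      metadata = metadata
    ),
    class = "trajectory"
  )
}

#' @export
length.trajectory <- function(x) dim(x$positions)[3]

#' Number of frames in a trajectory
#' @param traj a [trajectory()].
#' @export
n_frames <- function(traj) dim(traj$positions)[3]

#' Extract one frame of a trajectory as a system state
#' @param traj a [trajectory()].
#' @param i frame index.
#' @export
frame_state <- function(traj, i) {
  system_state(
    traj$positions[, , i],
    if (!is.null(traj$velocities)) traj$velocities[, , i] else NULL,
    traj$topology, traj$confinement,
    time = traj$times[i]
  )
}

# build a trajectory from a list of position matrices
trajectory_from_frames <- function(frames, times, topology, confinement,
                                   vel_frames = NULL, metadata = list()) {
  n <- sum(topology$n_monomers)
  nf <- length(frames)
  pos <- array(
    if (nf) unlist(frames, use.names = FALSE) else numeric(),
    dim = c(n, 3, nf)
  )
  vel <- NULL
  if (!is.null(vel_frames) && length(vel_frames) == nf && nf > 0) {
    vel <- array(unlist(vel_frames, use.names = FALSE), dim = c(n, 3, nf))
  }
  trajectory(pos, times, topology, confinement, vel, metadata)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> %d frames x %d monomers (%d chains), %s, dt_sample = %s tau0\n",
    n_frames(x), dim(x$positions)[1], nrow(x$topology),
    x$confinement$shape, format(x$sampling_interval)
  ))
  invisible(x)
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf(
    "<system_state> %d monomers, %d chains, %s, t = %g tau0\n",
    nrow(x$positions), nrow(x$topology), x$confinement$shape, x$time
  ))
  invisible(x)
}

#' @export
print.forcefield_params <- function(x, ...) {
  cat(sprintf(
    "<forcefield_params> K = %g, R0 = %g, eps = %g, sigma = %g, rc = %g, wall eps = %g\n",
    x$fene_k, x$fene_r0, x$lj_epsilon, x$lj_sigma, x$lj_cutoff, x$wall_epsilon
  ))
  invisible(x)
}
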