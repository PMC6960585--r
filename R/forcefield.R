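# User-facing energy/force evaluation.  The heavy lifting lives in compiled
# kernels (cell-list neighbour search, fixed accumulation order: bond, pair,
# angle, wall); these wrappers expose the individual potential terms and the
# assembled breakdown.

#' FENE bond energy
#'
#' `U(r) = -K R0^2 / 2 * ln(1 - (r/R0)^2)`: finitely extensible nonlinear
#' elastic bond, divergent at `R0` so bonds can never stretch far enough for
#' chains to cross.
#'
#' @param r bond length(s), `0 <= r < fene_r0`.
#' @param ff force-field parameters.
#' @return Energy in k_B T.
#' @examples
#' fene_energy(0.97) # 18.28
#' @export
fene_energy <- function(r, ff = forcefield_params()) {
  if (any(r < 0)) abort("bond length must be non-negative")
  if (any(r >= ff$fene_r0)) {
    abort(sprintf(
      "bond overstretched: r = %.4f >= R0 = %.4f (integration blow-up)",
      max(r), ff$fene_r0
    ))
  }
  -0.5 * ff$fene_k * ff$fene_r0^2 * log(1 - (r / ff$fene_r0)^2)
}

#' WCA pair energy
#'
#' The purely repulsive shifted-truncated Lennard-Jones potential,
#' `4 eps [(sigma/r)^12 - (sigma/r)^6 + 1/4]` up to the cutoff
#' `rc = 2^(1/6) sigma` and zero beyond, continuous at the cutoff. Applied
#' to bonded and non-bonded pairs alike.
#'
#' @param r pair distance(s), positive.
#' @param ff force-field parameters.
#' @return Energy in k_B T.
#' @export
wca_energy <- function(r, ff = forcefield_params()) {
  if (any(r <= 0)) abort("pair distance must be positive (r = 0 is singular)")
  ifelse(r > ff$lj_cutoff, 0,
    4 * ff$lj_epsilon *
      ((ff$lj_sigma / r)^12 - (ff$lj_sigma / r)^6 + 0.25)
  )
}

#' Bending energy at one monomer
#'
#' `U = k_b (1 + cos theta)` where `theta` is the interior angle between the
#' two bonds meeting at a monomer — `pi` when the bonds are collinear, so a
#' straight chain costs nothing and curvature is penalised. A rigid planar
#' N-gon pays `k_b (1 - cos(2 pi / N))` per vertex.
#'
#' @param theta interior bond angle(s) in radians, in `[0, pi]`.
#' @param kb bending constant.
#' @return Energy in k_B T.
#' @export
bending_energy <- function(theta, kb) {
  if (any(theta < 0 | theta > pi)) abort("theta must lie in [0, pi]")
  kb * (1 + cos(theta))
}

#' Wall energy of a single monomer
#'
#' Smooth mode evaluates the WCA form on the radial gap `d = R - |r|`, so
#' monomer centres are excluded beyond `|r| = R - sigma` at k_B T-scale
#' energies; particulate mode sums the pair potential over the explicit
#' wall-particle shell.
#'
#' @param position a 3-vector (or `n x 3` matrix).
#' @param confinement a sphere confinement.
#' @param ff force-field parameters.
#' @return Energy in k_B T (vector for a matrix of positions).
#' @export
wall_energy <- function(position, confinement, ff = forcefield_params()) {
  if (confinement$shape != "sphere") abort("wall_energy requires sphere mode")
  p <- if (is.matrix(position)) position else matrix(position, 1, 3)
  r <- sqrt(rowSums(p^2))
  if (any(r >= confinement$radius)) {
    abort(sprintf(
      "monomer escaped the sphere: |r| = %.4f >= R = %.4f",
      max(r), confinement$radius
    ))
  }
  if (confinement$wall_style == "smooth") {
    gap <- confinement$radius - r
    ifelse(gap > ff$lj_cutoff, 0, 4 * ff$wall_epsilon *
      ((ff$lj_sigma / gap)^12 - (ff$lj_sigma / gap)^6 + 0.25))
  } else {
    w <- confinement$wall_points
    vapply(seq_len(nrow(p)), function(i) {
      d <- sqrt(colSums((t(w) - p[i, ])^2))
      d <- d[d <= ff$lj_cutoff]
      if (!length(d)) {
        return(0)
      }
      sum(4 * ff$wall_epsilon *
        ((ff$lj_sigma / d)^12 - (ff$lj_sigma / d)^6 + 0.25))
    }, numeric(1))
  }
}

#' Total energy breakdown of a state
#'
#' Sums the FENE, pair (WCA), bending and wall terms over the whole system.
#' Bonded pairs contribute to both the FENE and the pair term.
#'
#' @param state a [system_state()].
#' @param ff force-field parameters.
#' @param use_cells use the cell-list neighbour search (identical result to
#'   the all-pairs loop; set `FALSE` to force brute-force evaluation).
#' @return An `energy_breakdown`: list with `fene`, `pair`, `bending`,
#'   `wall`, `total`.
#' @export
total_energy <- function(state, ff = forcefield_params(), use_cells = TRUE) {
  al <- angle_list(state$topology)
  e <- energy_cpp(
    state$positions, bond_list(state$topology) - 1L, al$triplets - 1L, al$k,
    unclass(ff), conf_cpp(state$confinement),
    use_cells = use_cells
  )
  structure(e, class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf(
    "<energy_breakdown> fene %.4g | pair %.4g | bending %.4g | wall %.4g | total %.4g\n",
    x$fene, x$pair, x$bending, x$wall, x$total
  ))
  invisible(x)
}

#' @export
tidy.energy_breakdown <- function(x, ...) {
  tibble::tibble(
    term = c("fene", "pair", "bending", "wall", "total"),
    energy = c(x$fene, x$pair, x$bending, x$wall, x$total)
  )
}

#' Forces on every monomer
#'
#' Analytic gradients of all potential terms, `F = -grad U`. Periodic mode
#' applies the minimum-image convention; sphere mode adds the wall force.
#'
#' @inheritParams total_energy
#' @return An `n x 3` matrix of forces.
#' @export
forces <- function(state, ff = forcefield_params(), use_cells = TRUE) {
  al <- angle_list(state$topology)
  forces_cpp(
    state$positions, bond_list(state$topology) - 1L, al$triplets - 1L, al$k,
    unclass(ff), conf_cpp(state$confinement),
    use_cells = use_cells
  )
}

# per-chain bending energy of one frame's coordinates (vectorised)
chain_bending_energies <- function(pos, top, box = NULL) {
  al <- angle_list(top)
  if (nrow(al$triplets) == 0) {
    return(rep(0, nrow(top)))
  }
  a <- pos[al$triplets[, 1], , drop = FALSE] - pos[al$triplets[, 2], , drop = FALSE]
  b <- pos[al$triplets[, 3], , drop = FALSE] - pos[al$triplets[, 2], , drop = FALSE]
  if (!is.null(box)) {
    a <- a - box * round(a / box)
    b <- b - box * round(b / box)
  }
  ct <- rowSums(a * b) / (sqrt(rowSums(a^2)) * sqrt(rowSums(b^2)))
  ct <- pmin(1, pmax(-1, ct))
  e <- al$k * (1 + ct)
  # map angles back to chains
  sl <- chain_slices(top)
  n_ang <- ifelse(sl$kind == "ring", sl$n, pmax(0L, sl$n - 2L))
  grp <- factor(rep(seq_len(nrow(top)), n_ang), levels = seq_len(nrow(top)))
  out <- tapply(e, grp, sum, default = 0)
  as.numeric(ifelse(is.na(out), 0, out))
}
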