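# Trajectory and state I/O: XYZ blocks and LAMMPS-style dump files (the
# interoperable dialects for bead-spring MD), plus a LAMMPS data file for
# restarts and a JSON results manifest.  Coordinates round-trip at full
# double precision (17 significant digits).

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

#' Write / read trajectories
#'
#' `write_trajectory()` writes either multi-frame XYZ
#' (`N` / comment / `El x y z` blocks) or a LAMMPS dump with
#' `ITEM:` headers and `id mol type x y z vx vy vz` columns; the molecule id
#' encodes chain membership and the type distinguishes species (1 = long,
#' 2 = short). `read_trajectory()` inverts either format bit-faithfully for
#' coordinates at the written precision; reading a dump reconstructs the
#' chain partition from the molecule ids (bending constants and kinds are
#' not stored by these formats and default to ring/0 unless a `topology` is
#' supplied).
#'
#' @param traj a [trajectory()] (or [system_state()], written as one frame).
#' @param path output file.
#' @param format `"xyz"` or `"lammps_dump"`.
#' @return `path` invisibly; `read_trajectory()` returns a [trajectory()].
#' @export
write_trajectory <- function(traj, path, format = c("xyz", "lammps_dump")) {
  format <- match.arg(format)
  if (inherits(traj, "system_state")) traj <- as_trajectory(traj)
  stopifnot(inherits(traj, "trajectory"))
  at <- atom_table(traj$topology)
  type <- ifelse(at$species == "long", 1L, 2L)
  n <- nrow(at)
  con <- file(path, "w")
  on.exit(close(con))
  nf <- n_frames(traj)
  if (format == "xyz") {
    if (nf == 0) {
      writeLines(c("0", "empty trajectory"), con)
      return(invisible(path))
    }
    for (f in seq_len(nf)) {
      pos <- traj$positions[, , f]
      writeLines(as.character(n), con)
      writeLines(sprintf("frame %d time %s", f, fmt_num(traj$times[f])), con)
      writeLines(
        paste("C", fmt_num(pos[, 1]), fmt_num(pos[, 2]), fmt_num(pos[, 3])),
        con
      )
    }
  } else {
    if (nf == 0) {
      writeLines(c("ITEM: TIMESTEP", "0", "ITEM: NUMBER OF ATOMS", "0"), con)
      return(invisible(path))
    }
    lims <- if (traj$confinement$shape == "sphere") {
      c(-traj$confinement$radius, traj$confinement$radius)
    } else {
      c(0, traj$confinement$box_edge)
    }
    for (f in seq_len(nf)) {
      pos <- traj$positions[, , f]
      vel <- if (!is.null(traj$velocities)) traj$velocities[, , f] else matrix(0, n, 3)
      writeLines(c(
        "ITEM: TIMESTEP", fmt_num(traj$times[f]),
        "ITEM: NUMBER OF ATOMS", as.character(n),
        "ITEM: BOX BOUNDS pp pp pp",
        paste(fmt_num(lims[1]), fmt_num(lims[2])),
        paste(fmt_num(lims[1]), fmt_num(lims[2])),
        paste(fmt_num(lims[1]), fmt_num(lims[2])),
        "ITEM: ATOMS id mol type x y z vx vy vz"
      ), con)
      writeLines(paste(
        at$atom, at$chain, type,
        fmt_num(pos[, 1]), fmt_num(pos[, 2]), fmt_num(pos[, 3]),
        fmt_num(vel[, 1]), fmt_num(vel[, 2]), fmt_num(vel[, 3])
      ), con)
    }
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @param topology optional [topology()] carrying chain kinds and bending
#'   constants that the file formats do not store.
#' @param confinement optional confinement for the returned trajectory.
#' @export
read_trajectory <- function(path, format = c("xyz", "lammps_dump"),
                            topology = NULL, confinement = NULL) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "xyz") {
    frames <- list()
    times <- numeric()
    i <- 1
    while (i <= length(lines)) {
      n <- as.integer(lines[i])
      if (is.na(n)) break
      if (n == 0) break
      tm <- suppressWarnings(as.numeric(sub(".*time ", "", lines[i + 1])))
      block <- lines[(i + 2):(i + 1 + n)]
      m <- do.call(rbind, strsplit(trimws(block), "\\s+"))
      frames[[length(frames) + 1]] <- matrix(as.numeric(m[, 2:4]), n, 3)
      times <- c(times, if (is.na(tm)) length(frames) else tm)
      i <- i + 2 + n
    }
    if (!length(frames)) {
      top <- topology %||% abort("empty XYZ file needs an explicit topology")
      return(trajectory_from_frames(
        list(), numeric(), top,
        confinement %||% confinement_sphere(20)
      ))
    }
    n <- nrow(frames[[1]])
    top <- topology %||% topology(tibble::tibble(
      kind = "linear", n_monomers = n, bending_k = 0, species = "long"
    ))
    conf <- confinement %||%
      confinement_sphere(max(1, ceiling(max(abs(unlist(frames))) + 1)))
    trajectory_from_frames(frames, times, top, conf)
  } else {
    hdr <- which(lines == "ITEM: TIMESTEP")
    frames <- list()
    vels <- list()
    times <- numeric()
    chain_ids <- NULL
    types <- NULL
    lims <- NULL
    for (h in hdr) {
      tm <- as.numeric(lines[h + 1])
      n <- as.integer(lines[h + 3])
      if (n == 0) next
      lims <- as.numeric(strsplit(trimws(lines[h + 5]), "\\s+")[[1]])
      atoms_at <- grep("^ITEM: ATOMS", lines[h:min(h + 8, length(lines))])[1] + h - 1
      block <- lines[(atoms_at + 1):(atoms_at + n)]
      m <- do.call(rbind, strsplit(trimws(block), "\\s+"))
      ord <- order(as.integer(m[, 1]))
      m <- m[ord, , drop = FALSE]
      frames[[length(frames) + 1]] <- matrix(as.numeric(m[, 4:6]), n, 3)
      vels[[length(vels) + 1]] <- matrix(as.numeric(m[, 7:9]), n, 3)
      chain_ids <- as.integer(m[, 2])
      types <- as.integer(m[, 3])
      times <- c(times, tm)
    }
    if (!length(frames)) {
      top <- topology %||% abort("empty dump needs an explicit topology")
      return(trajectory_from_frames(
        list(), numeric(), top,
        confinement %||% confinement_sphere(20)
      ))
    }
    top <- topology %||% {
      rl <- rle(chain_ids)
      topology(tibble::tibble(
        kind = "ring", n_monomers = rl$lengths, bending_k = 0,
        species = ifelse(types[cumsum(rl$lengths)] == 1L, "long", "short")
      ))
    }
    conf <- confinement %||% {
      if (!is.null(lims) && lims[1] < 0) {
        confinement_sphere(lims[2])
      } else {
        confinement_box(lims[2] - lims[1])
      }
    }
    trajectory_from_frames(frames, times, top, conf, vels)
  }
}

#' Write a LAMMPS data (restart) file
#'
#' Atoms in `molecular` style with bonds and angles, enough to restart or
#' inspect a state in external tools.
#'
#' @param state a [system_state()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_lammps_data <- function(state, path) {
  at <- atom_table(state$topology)
  bonds <- bond_list(state$topology)
  al <- angle_list(state$topology)
  n <- nrow(at)
  lim <- if (state$confinement$shape == "sphere") {
    c(-state$confinement$radius, state$confinement$radius)
  } else {
    c(0, state$confinement$box_edge)
  }
  type <- ifelse(at$species == "long", 1L, 2L)
  lines <- c(
    "ringmix data file", "",
    sprintf("%d atoms", n),
    sprintf("%d bonds", nrow(bonds)),
    sprintf("%d angles", nrow(al$triplets)),
    "", "2 atom types", "1 bond types", "2 angle types", "",
    sprintf("%s %s xlo xhi", fmt_num(lim[1]), fmt_num(lim[2])),
    sprintf("%s %s ylo yhi", fmt_num(lim[1]), fmt_num(lim[2])),
    sprintf("%s %s zlo zhi", fmt_num(lim[1]), fmt_num(lim[2])),
    "", "Masses", "", "1 1.0", "2 1.0", "", "Atoms", "",
    paste(at$atom, at$chain, type,
      fmt_num(state$positions[, 1]), fmt_num(state$positions[, 2]),
      fmt_num(state$positions[, 3])
    ),
    "", "Velocities", "",
    paste(at$atom,
      fmt_num(state$velocities[, 1]), fmt_num(state$velocities[, 2]),
      fmt_num(state$velocities[, 3])
    ),
    "", "Bonds", "",
    paste(seq_len(nrow(bonds)), 1L, bonds[, 1], bonds[, 2])
  )
  if (nrow(al$triplets) > 0) {
    ang_type <- ifelse(al$k >= 50, 2L, 1L)
    lines <- c(
      lines, "", "Angles", "",
      paste(
        seq_len(nrow(al$triplets)), ang_type,
        al$triplets[, 1], al$triplets[, 2], al$triplets[, 3]
      )
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Results manifest
#'
#' A JSON record tying outputs to the exact configuration and seed that
#' produced them: config snapshot, per-observable entries (path +
#' parameters), package version and wall-clock metadata. Config + seed
#' suffice to regenerate every referenced file.
#'
#' @param config a resolved config (from [validate_config()]) or raw list.
#' @param outputs named list of entries, each a list with at least `path`
#'   and `parameters`.
#' @param path file to write.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(config, outputs, path) {
  cfg <- if (!is.null(config$system)) {
    if (inherits(config$forcefield, "forcefield_params")) {
      serialize_config(config)
    } else {
      config
    }
  } else {
    config
  }
  manifest <- list(
    config = cfg,
    seed = cfg$schedule$seed %||% cfg$system$seed,
    outputs = outputs,
    software = list(
      package = "ringmix",
      version = as.character(utils::packageVersion("ringmix"))
    ),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
    digits = NA
  )
  invisible(manifest)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path)
}
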