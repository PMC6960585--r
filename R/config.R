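# Configuration schema: a YAML/JSON document with top-level keys
# system / forcefield / schedule / output, resolved into typed objects.

#' Run schedule
#'
#' Timestep, equilibration and production lengths, sampling interval and an
#' optional reheat-annealing ladder. Times are in tau0; the sampling interval
#' is in integration steps.
#'
#' @param timestep integration timestep in tau0.
#' @param equilibration_time,production_time durations in tau0.
#' @param sample_interval sampling interval in steps.
#' @param anneal optional data frame / list of stages with fields `tstar` and
#'   `duration` (tau0), run before equilibration at the target temperature.
#' @param seed integer seed controlling every stochastic element of a run.
#' @param tstar target reduced temperature of the production ensemble.
#' @return An object of class `run_schedule`.
#' @export
run_schedule <- function(timestep = 0.006, equilibration_time = 0,
                         production_time = 0, sample_interval = 1e4,
                         anneal = NULL, seed = 1L, tstar = 1.0) {
  if (timestep <= 0) abort("timestep must be positive")
  if (equilibration_time < 0 || production_time < 0) {
    abort("durations must be non-negative")
  }
  if (sample_interval < 1) abort("sample_interval must be >= 1 step")
  if (!is.null(anneal)) {
    anneal <- tibble::as_tibble(anneal)
    if (!all(c("tstar", "duration") %in% names(anneal))) {
      abort("anneal stages need fields 'tstar' and 'duration'")
    }
  }
  structure(
    list(
      timestep = timestep, equilibration_time = equilibration_time,
      production_time = production_time,
      sample_interval = as.integer(sample_interval),
      anneal = anneal, seed = as.integer(seed), tstar = tstar
    ),
    class = "run_schedule"
  )
}

#' Validate and resolve a configuration document
#'
#' Reads a structured config (a YAML/JSON path or an already-parsed list)
#' with top-level keys `system`, `forcefield`, `schedule`, and resolves it
#' into typed objects. The short-species chain count is derived from the
#' requested number density via [count_short_chains()] unless given
#' explicitly. Densities above 0.6 are accepted with a warning: beyond that
#' the model's rings deform appreciably.
#'
#' @param raw a file path or a named list.
#' @return A list with elements `forcefield`, `topology`, `confinement`,
#'   `schedule`, `system` (the resolved system block, including the achieved
#'   density).
#' @examples
#' cfg <- validate_config(default_config())
#' cfg$system$m_short # 1290 at rho = 0.4, R = 20
#' @export
validate_config <- function(raw) {
  if (is.character(raw) && length(raw) == 1) {
    raw <- yaml::read_yaml(raw)
  }
  if (!is.list(raw)) abort("config must be a file path or a named list")
  sys <- raw$system
  if (is.null(sys)) abort("config is missing the 'system' block")
  need <- function(block, field, blockname) {
    v <- block[[field]]
    if (is.null(v)) abort(sprintf("config field %s/%s is missing", blockname, field))
    if (is.numeric(v) && (!is.finite(v) || v <= 0)) {
      abort(sprintf("config field %s/%s must be positive", blockname, field))
    }
    v
  }
  rho <- need(sys, "rho", "system")
  if (rho > 0.6) {
    warn(sprintf(
      "rho = %.2f exceeds 0.6, the highest density at which rings stay undeformed",
      rho
    ))
  }

  ffb <- raw$forcefield %||% list()
  ff <- forcefield_params(
    fene_k = ffb$fene_k %||% 30, fene_r0 = ffb$fene_r0 %||% 1.5,
    lj_epsilon = ffb$lj_epsilon %||% 1, lj_sigma = ffb$lj_sigma %||% 1,
    lj_cutoff = ffb$lj_cutoff %||% 2^(1 / 6),
    wall_epsilon = ffb$wall_epsilon %||% 1
  )

  shape <- sys$confinement %||% "sphere"
  conf <- if (identical(shape, "periodic_box")) {
    confinement_box(need(sys, "box_edge", "system"))
  } else {
    confinement_sphere(
      radius = sys$radius %||% 20,
      wall_style = sys$wall_style %||% "smooth"
    )
  }

  m_long <- need(sys, "m_long", "system")
  n_long <- need(sys, "n_long", "system")
  n_short <- need(sys, "n_short", "system")
  m_short <- sys$m_short %||%
    count_short_chains(rho, conf, m_long, n_long, n_short)
  top <- binary_mixture_topology(
    m_long = m_long, n_long = n_long,
    kb_long = sys$kb_long %||% 0,
    m_short = m_short, n_short = n_short,
    kb_short = sys$kb_short %||% 50,
    long_kind = sys$long_kind %||% "ring"
  )
  achieved <- sum(top$n_monomers) / confinement_volume(conf)

  sch <- raw$schedule %||% list()
  schedule <- run_schedule(
    timestep = sch$timestep %||% 0.006,
    equilibration_time = sch$equilibration_time %||% 0,
    production_time = sch$production_time %||% 0,
    sample_interval = sch$sample_interval %||% 1e4,
    anneal = sch$anneal,
    seed = sch$seed %||% sys$seed %||% 1L,
    tstar = sch$tstar %||% 1.0
  )

  list(
    forcefield = ff, topology = top, confinement = conf, schedule = schedule,
    system = list(
      rho = rho, rho_achieved = achieved, m_long = m_long, n_long = n_long,
      m_short = m_short, n_short = n_short,
      kb_long = sys$kb_long %||% 0, kb_short = sys$kb_short %||% 50,
      long_kind = sys$long_kind %||% "ring",
      confinement = shape,
      radius = conf$radius, box_edge = conf$box_edge,
      seed = schedule$seed
    )
  )
}

#' Serialise a resolved configuration back to its document form
#'
#' Inverse of [validate_config()] up to derived fields: round-tripping a
#' document through validate -> serialize -> validate yields the same
#' resolved objects.
#'
#' @param cfg the list returned by [validate_config()].
#' @param path optional file; when given, written as YAML.
#' @return The raw config list (invisibly when written to a file).
#' @export
serialize_config <- function(cfg, path = NULL) {
  ff <- cfg$forcefield
  sc <- cfg$schedule
  raw <- list(
    system = list(
      rho = cfg$system$rho,
      confinement = cfg$system$confinement,
      radius = cfg$system$radius,
      box_edge = cfg$system$box_edge,
      wall_style = cfg$confinement$wall_style,
      m_long = cfg$system$m_long, n_long = cfg$system$n_long,
      m_short = cfg$system$m_short, n_short = cfg$system$n_short,
      kb_long = cfg$system$kb_long, kb_short = cfg$system$kb_short,
      long_kind = cfg$system$long_kind,
      seed = cfg$system$seed
    ),
    forcefield = unclass(ff),
    schedule = list(
      timestep = sc$timestep,
      equilibration_time = sc$equilibration_time,
      production_time = sc$production_time,
      sample_interval = sc$sample_interval,
      anneal = if (!is.null(sc$anneal)) as.list(sc$anneal) else NULL,
      seed = sc$seed, tstar = sc$tstar
    )
  )
  raw$system <- raw$system[!vapply(raw$system, is.null, logical(1))]
  if (!is.null(path)) {
    yaml::write_yaml(raw, path)
    return(invisible(raw))
  }
  raw
}

#' Default study configuration
#'
#' The reference composition of the confined binary ring mixture: a hard
#' sphere of radius 20 sigma at number density 0.4, ten long rings of 50
#' monomers, short rings of 10 monomers filling the remaining density, short
#' rings stiff (`kb_short = 50`).
#'
#' @param ... fields overriding the `system` block.
#' @return A raw config list suitable for [validate_config()].
#' @export
default_config <- function(...) {
  sys <- list(
    rho = 0.4, confinement = "sphere", radius = 20,
    m_long = 10, n_long = 50, kb_long = 50,
    n_short = 10, kb_short = 50, long_kind = "ring", seed = 1L
  )
  over <- list(...)
  sys[names(over)] <- over
  list(system = sys)
}
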