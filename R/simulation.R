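# Orchestration: configuration presets, the primary and secondary response
# runs, and the assembly of engine output into tidy tables.

#' Simulation configuration
#'
#' Bundles everything that determines a run. Two presets are provided:
#' `"ci"`, a scaled-down setting (60 x 60 lattice, 12,000 MCS, 10 naive
#' cells and 1 APC) sized so that a run takes well under a minute while
#' still exhibiting the full expansion / contraction / memory sequence; and
#' `"full"`, the full-scale setting (150 x 150 lattice, 30,000 one-minute
#' MCS covering day 4 to day 24.8 post-infection, 30 naive cells and 3
#' APCs).
#'
#' @param preset `"ci"` (default) or `"full"`.
#' @param L Lattice side in nodes.
#' @param n_mcs Number of Monte Carlo steps; one MCS is `minutes_per_mcs`
#'   simulated minutes.
#' @param n_naive,n_apc,n_memory Initial cell counts. `n_memory` is used by
#'   [run_secondary()] which replaces the naive pool with memory cells.
#' @param minutes_per_mcs Simulated minutes per MCS (default 1).
#' @param start_day Day post-infection at MCS 0 (default 4).
#' @param snapshot_every,cell_snapshot_every Output cadence in MCS for
#'   population counts and per-cell molecular rows.
#' @param molecular,field,potts,thresholds Component parameter sets; see
#'   [molecular_params()], [field_params()], [potts_config()],
#'   [cd8_thresholds()].
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(preset = c("ci", "full"),
                       L = NULL, n_mcs = NULL, n_naive = NULL, n_apc = NULL,
                       n_memory = NULL,
                       minutes_per_mcs = 1, start_day = 4,
                       snapshot_every = 60L, cell_snapshot_every = 720L,
                       molecular = molecular_params(),
                       field = field_params(),
                       potts = potts_config(),
                       thresholds = cd8_thresholds()) {
  preset <- match.arg(preset)
  def <- if (preset == "full")
    list(L = 150L, n_mcs = 30000L, n_naive = 30L, n_apc = 3L, n_memory = 30L)
  else
    list(L = 60L, n_mcs = 12000L, n_naive = 10L, n_apc = 1L, n_memory = 10L)
  cfg <- list(
    preset = preset,
    L = as.integer(L %||% def$L),
    n_mcs = as.integer(n_mcs %||% def$n_mcs),
    n_naive = as.integer(n_naive %||% def$n_naive),
    n_apc = as.integer(n_apc %||% def$n_apc),
    n_memory = as.integer(n_memory %||% def$n_memory),
    minutes_per_mcs = minutes_per_mcs,
    start_day = start_day,
    snapshot_every = as.integer(snapshot_every),
    cell_snapshot_every = as.integer(cell_snapshot_every),
    molecular = molecular, field = field, potts = potts,
    thresholds = thresholds
  )
  if (cfg$L < 20) stop("lattice side must be at least 20 nodes")
  if (any(c(cfg$n_naive, cfg$n_apc, cfg$n_memory) < 0)) stop("counts must be >= 0")
  structure(cfg, class = c("sim_config", "list"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

engine_config <- function(config, mode, memory_state) {
  th <- config$thresholds
  list(
    L = config$L, n_mcs = config$n_mcs,
    minutes_per_mcs = config$minutes_per_mcs,
    n_naive = if (mode == "primary") config$n_naive else 0L,
    n_apc = config$n_apc,
    n_memory = if (mode == "secondary") config$n_memory else 0L,
    snapshot_every = config$snapshot_every,
    cell_snapshot_every = config$cell_snapshot_every,
    start_day = config$start_day,
    molecular = config$molecular,
    field = config$field,
    potts = unclass(config$potts),
    rules = list(IL2R_th = th$IL2R_th, Tbet_th = th$Tbet_th,
                 Eomes_th = th$Eomes_th, Caspases_th = th$Caspases_th,
                 m = th$m, memory_divides = th$memory_divides),
    memory_state = as.numeric(memory_state)
  )
}

event_labels <- c("pre_activation", "activation", "division", "birth",
                  "memory_conversion", "apoptosis", "apc_death")

assemble_sim <- function(raw, config, mode) {
  day0 <- config$start_day
  mpm <- config$minutes_per_mcs
  pop <- tibble::as_tibble(raw$population)
  pop$day <- day0 + pop$mcs * mpm / 1440
  pop$total_cd8 <- pop$naive + pop$pre_activated + pop$activated +
    pop$effector + pop$memory
  pop <- pop[, c("mcs", "day", "naive", "pre_activated", "activated",
                 "effector", "memory", "apc", "total_cd8")]
  cells <- tibble::as_tibble(raw$cells)
  cells$type <- type_label(cells$type)
  cells$day <- day0 + cells$mcs * mpm / 1440
  events <- tibble::as_tibble(raw$events)
  events$event <- event_labels[events$code]
  events$day <- day0 + events$mcs * mpm / 1440
  events <- events[, c("mcs", "day", "id", "event", "value")]
  final_cells <- tibble::tibble(
    id = raw$final_cells$id,
    type = type_label(raw$final_cells$type),
    k = raw$final_cells$k,
    area = raw$final_cells$area
  )
  fm <- raw$final_cells$mol
  colnames(fm) <- mol_vars
  final_cells <- dplyr::bind_cols(final_cells, tibble::as_tibble(fm))
  structure(list(
    population = pop, cells = cells, events = events,
    final_cells = final_cells,
    final_sigma = raw$final_sigma, final_field = raw$final_field,
    stats = raw$stats, config = config, mode = mode
  ), class = "cd8_sim")
}

run_mode <- function(config, mode) {
  mem_state <- if (mode == "secondary")
    as.numeric(asymptotic_memory_state(config$molecular)[1, ])
  else rep(0, 6)
  raw <- cpp_run_simulation(engine_config(config, mode, mem_state))
  if (raw$stats$mol_steps > 0 &&
      raw$stats$clipped / (6 * raw$stats$mol_steps) > 0.001)
    warning("more than 0.1% of molecular integration steps clipped a negative value")
  assemble_sim(raw, config, mode)
}

#' Run a primary CD8 T-cell response
#'
#' Seeds naive CD8 T-cells and APCs at random non-overlapping positions and
#' iterates the coupled model: per MCS one Potts Monte Carlo step, contact
#' and environment extraction, a molecular ODE step per cell, an IL2 field
#' step, then the differentiation / division / apoptosis rules. Fully
#' reproducible given `set.seed()`.
#'
#' @param config A [sim_config()].
#' @return A `cd8_sim` object: list with tidy `population`, `cells` and
#'   `events` tables, the final lattice/field/cell state, engine statistics
#'   and the configuration. Use [tidy()], [glance()] and [autoplot()] on it.
#' @export
run_primary <- function(config = sim_config()) {
  run_mode(config, "primary")
}

#' Run a secondary (memory) response
#'
#' As [run_primary()] but the initial CD8 T-cells are memory cells carrying
#' the asymptotic molecular profile of resting memory (see
#' [asymptotic_memory_state()]); they may bind an APC, become pre-activated
#' and re-enter the differentiation scheme. Their sustained Eomes keeps
#' their IL2 receptor level above a naive cell's, so the activation
#' threshold is reached sooner than in a primary response.
#'
#' @param config A [sim_config()]; `n_memory` sets the initial pool size.
#' @return A `cd8_sim` object.
#' @export
run_secondary <- function(config = sim_config()) {
  run_mode(config, "secondary")
}

#' Print a simulation
#'
#' @param x A `cd8_sim` object.
#' @param ... Unused.
#' @export
print.cd8_sim <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<cd8_sim: %s response, %d x %d lattice, %d MCS>\n",
              x$mode, x$config$L, x$config$L, x$config$n_mcs))
  cat(sprintf("  peak %d CD8 T-cells on day %.1f p.i.; %d memory cells at end (day %.1f)\n",
              g$peak_size, g$peak_day, g$final_memory, max(x$population$day)))
  invisible(x)
}
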