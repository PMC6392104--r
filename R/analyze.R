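# Analysis of simulation output: ranked Tbet profiles, run summaries and the
# unevenness sweep.

#' Summary statistics of a run
#'
#' Peak size and day, memory pool at requested days, efficiency ratio
#' (memory pool / peak size) and the contraction death fraction
#' (1 - population at end / peak).
#'
#' @param sim A `cd8_sim` object.
#' @param memory_days Days p.i. at which to report the memory count (days
#'   beyond the simulated range report the final count).
#' @return A one-row tibble.
#' @export
summarize_run <- function(sim, memory_days = c(25, 29)) {
  pop <- sim$population
  ipk <- which.max(pop$total_cd8)
  peak_size <- pop$total_cd8[ipk]
  peak_day <- pop$day[ipk]
  mem_at <- vapply(memory_days, function(d) {
    i <- which(pop$day >= d)[1]
    if (is.na(i)) utils::tail(pop$memory, 1) else pop$memory[i]
  }, numeric(1))
  frac_ae_peak <- (pop$activated[ipk] + pop$effector[ipk]) / max(peak_size, 1)
  out <- tibble::tibble(
    peak_size = peak_size,
    peak_day = peak_day,
    frac_activated_effector_at_peak = frac_ae_peak,
    final_size = utils::tail(pop$total_cd8, 1),
    final_memory = utils::tail(pop$memory, 1),
    contraction_death_fraction = 1 - utils::tail(pop$total_cd8, 1) / max(peak_size, 1),
    efficiency_ratio = mem_at[1] / max(peak_size, 1)
  )
  for (i in seq_along(memory_days))
    out[[paste0("memory_d", memory_days[i])]] <- mem_at[i]
  out
}

#' Ranked Tbet profile of a population snapshot
#'
#' Cells of one snapshot sorted by Tbet concentration, with their Eomes and
#' Caspase levels, plus a bimodality summary: counts below and above the
#' unstable fixed point of the autonomous Tbet equation, and the count
#' within a window around it (the trough between the two modes).
#'
#' @param sim A `cd8_sim` object, or a cells tibble with columns `Tb`, `E`,
#'   `Cas` (and `mcs` if `day`/`mcs` selection is used).
#' @param day Day p.i. of the snapshot (nearest recorded cell snapshot is
#'   used); default is the last one.
#' @param params Molecular parameters used for the unstable-point reference.
#' @param window Half-width of the trough window as a fraction of the
#'   unstable point (default 0.25).
#' @return A tibble sorted by `Tb` with `rank`, `Tb`, `E`, `Cas` and
#'   attributes `tb_unstable`, `n_below`, `n_above`, `n_trough`.
#' @export
tbet_profile <- function(sim, day = NULL, params = NULL, window = 0.25) {
  if (inherits(sim, "cd8_sim")) {
    params <- params %||% sim$config$molecular
    cells <- sim$cells
    if (nrow(cells) == 0) return(tibble::tibble(rank = integer(), Tb = numeric(),
                                                E = numeric(), Cas = numeric()))
    target <- if (is.null(day)) max(cells$day) else day
    pick <- cells$day[which.min(abs(cells$day - target))]
    cells <- cells[cells$day == pick, ]
  } else {
    cells <- tibble::as_tibble(sim)
    params <- params %||% molecular_params()
  }
  fp <- tbet_fixed_points(params)
  unstable <- fp$root[!fp$stable & fp$root > 0]
  tbu <- if (length(unstable)) unstable[1] else NA_real_
  cells <- cells[order(cells$Tb), ]
  out <- tibble::tibble(rank = seq_len(nrow(cells)), Tb = cells$Tb,
                        E = cells$E, Cas = cells$Cas)
  if ("type" %in% names(cells)) out$type <- cells$type
  attr(out, "tb_unstable") <- tbu
  if (!is.na(tbu)) {
    attr(out, "n_below") <- sum(out$Tb < tbu)
    attr(out, "n_above") <- sum(out$Tb >= tbu)
    attr(out, "n_trough") <- sum(abs(out$Tb - tbu) <= window * tbu)
  }
  out
}

#' Sweep the degree of unevenness of molecular partitioning
#'
#' Runs primary responses varying only `m`, the width of the stochastic
#' per-protein split at division (the asymmetric first division is not
#' modified), and summarises each run. Replicates differ only through the
#' RNG stream.
#'
#' @param config A [sim_config()].
#' @param m_values Degrees of unevenness in percent.
#' @param replicates Runs per value of `m`.
#' @return A tibble of class `cd8_sweep`: one row per (m, replicate) with
#'   the [summarize_run()] columns.
#' @export
sweep_unevenness <- function(config = sim_config(),
                             m_values = c(0, 10, 25, 50, 65, 80),
                             replicates = 5L) {
  if (any(m_values < 0 | m_values > 100)) stop("m values must lie in [0, 100]")
  if (replicates < 1) stop("replicates must be >= 1")
  rows <- purrr::map_dfr(m_values, function(m) {
    cfg <- config
    cfg$thresholds$m <- m
    purrr::map_dfr(seq_len(replicates), function(r) {
      s <- run_primary(cfg)
      dplyr::bind_cols(tibble::tibble(m = m, replicate = r), summarize_run(s))
    })
  })
  class(rows) <- c("cd8_sweep", class(rows))
  rows
}

#' Summarise a sweep by degree of unevenness
#'
#' @param sweep Output of [sweep_unevenness()].
#' @return One row per `m` with means and standard deviations of peak size,
#'   memory pool and efficiency ratio.
#' @export
summarize_sweep <- function(sweep) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(sweep), .data$m),
    peak_mean = mean(.data$peak_size), peak_sd = stats::sd(.data$peak_size),
    memory_mean = mean(.data$final_memory), memory_sd = stats::sd(.data$final_memory),
    efficiency_mean = mean(.data$efficiency_ratio),
    efficiency_sd = stats::sd(.data$efficiency_ratio),
    .groups = "drop"
  )
}
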