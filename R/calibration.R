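# Calibration distances between simulated and reference time series, the
# synthetic reference fixture, and a simple coordinate local search.

ref_types <- c("naive_pre", "act_eff", "memory")
ref_proteins <- c("IL2R", "Tbet", "Eomes")

#' Cell-type fraction distance between simulations and a reference
#'
#' For every (simulation, subject) pair, the absolute differences of
#' cell-type fractions are summed over the three gathered types
#' (naive/pre-activated, activated/effector, memory) and all shared time
#' steps; the result is averaged over pairs (prefactor
#' `1 / (#simulations * #subjects)`).
#'
#' @param sim Long tibble with columns `series` (simulation id), `day`,
#'   `type` (one of `"naive_pre"`, `"act_eff"`, `"memory"`) and `value`
#'   (fraction).
#' @param reference Same layout with `series` identifying subjects.
#' @return The distance (dimensionless, bounded by #types x #timesteps).
#' @export
d_cell <- function(sim, reference) {
  pairwise_abs_distance(sim, reference, ref_types, normalize = FALSE)
}

#' Normalised protein-level distance between simulations and a reference
#'
#' As [d_cell()] but over mean protein levels (IL2 receptors = activated +
#' non-activated, Tbet, Eomes), with each series first normalised by its own
#' maximum over the shared time steps, so the metric is invariant to
#' rescaling any one series. An all-zero series cannot be normalised; it is
#' left as zeros with a warning.
#'
#' @param sim Long tibble with columns `series`, `day`, `type` (one of
#'   `"IL2R"`, `"Tbet"`, `"Eomes"`) and `value`.
#' @param reference Same layout.
#' @return The distance.
#' @export
d_prot <- function(sim, reference) {
  pairwise_abs_distance(sim, reference, ref_proteins, normalize = TRUE)
}

pairwise_abs_distance <- function(sim, reference, lev, normalize) {
  sim <- tibble::as_tibble(sim)
  reference <- tibble::as_tibble(reference)
  for (d in list(sim, reference))
    if (!all(c("series", "day", "type", "value") %in% names(d)))
      stop("series tables need columns series, day, type, value")
  if (!setequal(unique(sim$type), unique(reference$type)))
    stop("simulation and reference type sets must match (canonical sets: ",
         paste(lev, collapse = ", "), ")")
  days <- sort(intersect(unique(sim$day), unique(reference$day)))
  if (!length(days)) stop("no shared time steps between simulation and reference")
  norm_one <- function(d) {
    d <- d[d$day %in% days, ]
    if (!normalize) return(d)
    key <- paste(d$series, d$type)
    for (k in unique(key)) {
      idx <- key == k
      mx <- max(d$value[idx])
      if (mx == 0) warning("all-zero series left unnormalised")
      else d$value[idx] <- d$value[idx] / mx
    }
    d
  }
  sim <- norm_one(sim)
  reference <- norm_one(reference)
  sims <- unique(sim$series)
  subs <- unique(reference$series)
  tot <- 0
  for (s in sims) for (v in subs) {
    a <- sim[sim$series == s, ]
    b <- reference[reference$series == v, ]
    j <- dplyr::inner_join(a, b, by = c("day", "type"), suffix = c("_s", "_v"))
    tot <- tot + sum(abs(j$value_s - j$value_v))
  }
  tot / (length(sims) * length(subs))
}

#' Combined calibration distance
#'
#' `D = D_cell + D_prot` plus the per-term breakdown.
#'
#' @param sim_cell,ref_cell Fraction series for [d_cell()].
#' @param sim_prot,ref_prot Protein series for [d_prot()].
#' @return A one-row tibble with `d_cell`, `d_prot` and `D`.
#' @export
calibration_distance <- function(sim_cell, ref_cell, sim_prot, ref_prot) {
  dc <- d_cell(sim_cell, ref_cell)
  dp <- d_prot(sim_prot, ref_prot)
  tibble::tibble(d_cell = dc, d_prot = dp, D = dc + dp)
}

#' Fractions and mean protein levels of a run, in reference layout
#'
#' Resamples a run's population fractions (types gathered as
#' naive/pre-activated, activated/effector, memory) and mean protein levels
#' (IL2R = R + LR, Tbet, Eomes) onto a daily grid, ready for [d_cell()] /
#' [d_prot()].
#'
#' @param sim A `cd8_sim` object.
#' @param days Days p.i. to sample (default: whole days covered by the run).
#' @param series Label for the `series` column.
#' @return A list with tibbles `cell` and `prot`.
#' @export
sim_reference_series <- function(sim, days = NULL, series = "sim1") {
  pop <- sim$population
  if (is.null(days)) days <- seq(ceiling(min(pop$day)), floor(max(pop$day)))
  tot <- pmax(pop$total_cd8, 1)
  at <- function(v) approx(pop$day, v, xout = days, rule = 2)$y
  cell <- tibble::tibble(
    series = series,
    day = rep(days, 3),
    type = rep(ref_types, each = length(days)),
    value = c(at((pop$naive + pop$pre_activated) / tot),
              at((pop$activated + pop$effector) / tot),
              at(pop$memory / tot))
  )
  cells <- sim$cells
  mean_by_day <- function(expr) {
    agg <- dplyr::summarise(dplyr::group_by(cells, .data$day),
                            v = mean(expr(.data)), .groups = "drop")
    approx(agg$day, agg$v, xout = days, rule = 2)$y
  }
  prot <- tibble::tibble(
    series = series,
    day = rep(days, 3),
    type = rep(ref_proteins, each = length(days)),
    value = c(mean_by_day(function(d) d$R + d$LR),
              mean_by_day(function(d) d$Tb),
              mean_by_day(function(d) d$E))
  )
  list(cell = cell, prot = prot)
}

#' Synthetic reference time series
#'
#' A smooth stand-in for in vivo calibration data, with the qualitative
#' shape of a murine CD8 T-cell response: the activated/effector fraction
#' exceeds 0.94 at the day-8 peak, memory dominates by day 22, IL2 receptor
#' level peaks on day 5, Tbet plateaus over days 6-8 then declines, and
#' Eomes rises monotonically to day 8. Small subject-level noise is added
#' per series. This fixture is synthetic; it is not measured data.
#'
#' @param seed RNG seed for the subject noise.
#' @param n_subjects Number of reference subjects.
#' @param days Days p.i.
#' @return A list with tibbles `cell` and `prot` in the layout of
#'   [d_cell()] / [d_prot()].
#' @export
make_reference_fixture <- function(seed = 1, n_subjects = 5, days = 4:22) {
  set.seed(seed)
  base_cell <- function(day) {
    naive <- exp(-(day - 4) / 0.8)
    memory <- 1 / (1 + exp(-(day - 15) / 1.8))
    act <- pmax(1 - naive - memory, 0)
    tot <- naive + memory + act
    rbind(naive, act, memory) / rep(tot, each = 3)
  }
  base_prot <- function(day) {
    il2r <- exp(-((day - 5) / 2.5)^2) + 0.35 / (1 + exp(-(day - 12) / 2))
    tbet <- (1 / (1 + exp(-(day - 5.5) / 0.7))) * (1 - 0.75 / (1 + exp(-(day - 10) / 1.8)))
    eomes <- 1 / (1 + exp(-(day - 9) / 2.5))
    rbind(il2r, tbet, eomes)
  }
  one_subject <- function(s) {
    bc <- base_cell(days)
    bp <- base_prot(days)
    jit <- function(x) pmax(x * (1 + stats::rnorm(length(x), 0, 0.015)), 0)
    bc <- apply(bc, 2, jit)
    bc <- sweep(bc, 2, pmax(colSums(bc), 1), "/") # keep fractions summing to <= 1
    bp <- apply(bp, 2, jit)
    list(
      cell = tibble::tibble(series = paste0("subject", s),
                            day = rep(days, each = 3),
                            type = rep(ref_types, length(days)),
                            value = as.numeric(bc)),
      prot = tibble::tibble(series = paste0("subject", s),
                            day = rep(days, each = 3),
                            type = rep(ref_proteins, length(days)),
                            value = as.numeric(bp))
    )
  }
  subj <- lapply(seq_len(n_subjects), one_subject)
  list(cell = dplyr::bind_rows(lapply(subj, `[[`, "cell")),
       prot = dplyr::bind_rows(lapply(subj, `[[`, "prot")))
}

#' Coordinate local search over selected parameters
#'
#' Minimises an objective (by default the combined calibration distance of a
#' scaled-down primary run against a reference) by cyclic coordinate
#' descent: each free parameter is multiplied by the candidate factors in
#' turn and a move is kept only when it improves the best objective, so the
#' best-so-far trace is non-increasing by construction.
#'
#' @param initial Named numeric vector of starting parameter values (a
#'   subset of [molecular_params()] names).
#' @param objective Function taking a full `molecular_params()` list and
#'   returning a scalar; the default runs one CI-preset primary response and
#'   returns `D` against `reference`.
#' @param reference A reference list as from [make_reference_fixture()]
#'   (used by the default objective).
#' @param budget Maximum objective evaluations (>= 1).
#' @param factors Multiplicative candidate steps.
#' @param config Simulation configuration for the default objective.
#' @return A list with `par` (best parameters), `value`, and `trace`
#'   (tibble of evaluations with the running best).
#' @export
local_search <- function(initial, objective = NULL,
                         reference = make_reference_fixture(),
                         budget = 20L, factors = c(0.5, 0.8, 1.25, 2),
                         config = sim_config()) {
  if (budget < 1) stop("budget must be >= 1")
  if (is.null(objective)) {
    objective <- function(params) {
      cfg <- config
      cfg$molecular <- params
      s <- run_primary(cfg)
      ser <- sim_reference_series(s)
      calibration_distance(ser$cell, reference$cell, ser$prot, reference$prot)$D
    }
  }
  mk <- function(par) do.call(molecular_params, as.list(par))
  par <- initial
  evals <- 0
  best <- objective(mk(par))
  evals <- evals + 1
  trace <- tibble::tibble(eval = 1L, value = best, best = best)
  repeat {
    improved <- FALSE
    for (nm in names(par)) {
      for (f in factors) {
        if (evals >= budget) break
        cand <- par
        cand[nm] <- cand[nm] * f
        val <- objective(mk(cand))
        evals <- evals + 1
        if (val < best) {
          best <- val
          par <- cand
          improved <- TRUE
        }
        trace <- dplyr::bind_rows(trace,
          tibble::tibble(eval = evals, value = val, best = best))
      }
      if (evals >= budget) break
    }
    if (!improved || evals >= budget) break
  }
  list(par = par, value = best, trace = trace)
}
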