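# The intracellular molecular network: six coupled ODEs per cell describing
# IL2 receptor turnover, the bistable Tbet positive-feedback loop, Fas
# engagement, Caspase accumulation and Eomes synthesis.

mol_vars <- c("R", "LR", "Tb", "Fs", "Cas", "E")
env_vars <- c("f_APC", "G", "H", "IL2cm", "Tbcm")

#' Construct a molecular state
#'
#' One row per cell, columns `R`, `LR`, `Tb`, `Fs`, `Cas`, `E` (mol/L). A
#' never-activated naive cell is the all-zero state.
#'
#' @param R,LR,Tb,Fs,Cas,E Concentrations (mol/L), recycled to a common length.
#' @return A tibble with the six concentration columns.
#' @export
molecular_state <- function(R = 0, LR = 0, Tb = 0, Fs = 0, Cas = 0, E = 0) {
  out <- tibble::tibble(R = R, LR = LR, Tb = Tb, Fs = Fs, Cas = Cas, E = E)
  if (any(as.matrix(out) < 0)) stop("concentrations must be non-negative")
  out
}

#' Construct per-cell environment inputs
#'
#' The five external drivers of the intracellular system: `f_APC` the number
#' of APCs bound to the cell, `G` the activation-history flag (0 for naive,
#' 1 once the cell has met an APC), `H` the Fas-engagement flag (1 for a
#' non-naive cell touching an effector or memory cell), `IL2cm` the
#' extracellular IL2 summed over the cell's membrane, and `Tbcm` the summed
#' Tbet of contacting effector/memory cells.
#'
#' @param f_APC,G,H,IL2cm,Tbcm See description; recycled to a common length.
#' @return A tibble with the five driver columns.
#' @export
environment_inputs <- function(f_APC = 0, G = 0, H = 0, IL2cm = 0, Tbcm = 0) {
  out <- tibble::tibble(f_APC = f_APC, G = G, H = H, IL2cm = IL2cm, Tbcm = Tbcm)
  if (any(out$f_APC < 0 | out$f_APC != round(out$f_APC)))
    stop("f_APC must be a non-negative integer")
  if (!all(out$G %in% c(0, 1)) || !all(out$H %in% c(0, 1)))
    stop("G and H must be 0/1 flags")
  if (any(out$IL2cm < 0) || any(out$Tbcm < 0))
    stop("IL2cm and Tbcm must be non-negative")
  out
}

as_mol_matrix <- function(state) {
  if (is.numeric(state) && length(state) == 6) state <- as.list(setNames(state, mol_vars))
  state <- tibble::as_tibble(state)
  if (!all(mol_vars %in% names(state)))
    stop("state must have columns ", paste(mol_vars, collapse = ", "))
  m <- as.matrix(state[mol_vars])
  if (any(m < 0)) stop("state concentrations must be non-negative")
  m
}

as_env_matrix <- function(env, n_rows) {
  if (is.numeric(env) && length(env) == 5) env <- as.list(setNames(env, env_vars))
  env <- tibble::as_tibble(env)
  if (!all(env_vars %in% names(env)))
    stop("env must have columns ", paste(env_vars, collapse = ", "))
  m <- as.matrix(env[env_vars])
  if (nrow(m) == 1 && n_rows > 1) m <- m[rep(1, n_rows), , drop = FALSE]
  if (nrow(m) != n_rows) stop("state and env must have matching rows")
  m
}

#' Right-hand side of the molecular network
#'
#' Evaluates d/dt of the six concentrations for each row of `state` under the
#' corresponding row of `env` (a single env row is recycled).
#'
#' @param state Data frame of concentrations (see [molecular_state()]).
#' @param env Data frame of drivers (see [environment_inputs()]).
#' @param params Parameters from [molecular_params()].
#' @return A tibble of derivatives with the same six columns, in mol/L/h.
#' @export
molecular_rhs <- function(state, env = environment_inputs(), params = molecular_params()) {
  sm <- as_mol_matrix(state)
  em <- as_env_matrix(env, nrow(sm))
  out <- cpp_molecular_rhs(sm, em, params)
  colnames(out) <- mol_vars
  tibble::as_tibble(out)
}

#' Advance the molecular state by a time step
#'
#' Fixed-step fourth-order Runge-Kutta over `dt` hours under a frozen
#' environment; the step is subdivided tenfold automatically when any
#' variable would move by more than 20 percent in one step, and negative
#' undershoots are clipped at zero.
#'
#' @inheritParams molecular_rhs
#' @param dt Step size in hours (default one Monte Carlo step, 1/60 h).
#' @param n_steps Number of consecutive steps to take.
#' @return A tibble of updated concentrations.
#' @export
step_molecular <- function(state, env = environment_inputs(),
                           params = molecular_params(), dt = 1 / 60,
                           n_steps = 1L) {
  if (dt <= 0) stop("dt must be positive")
  sm <- as_mol_matrix(state)
  em <- as_env_matrix(env, nrow(sm))
  res <- cpp_step_molecular(sm, em, params, dt, as.integer(n_steps))
  out <- res$state
  colnames(out) <- mol_vars
  if (res$steps > 0 && res$clipped / (6 * res$steps) > 0.001)
    warning("more than 0.1% of integration steps clipped a negative value")
  tibble::as_tibble(out)
}

tbet_autonomous <- function(x, params) {
  params$lam_T2 * x^params$n / (params$lam_T3^params$n + x^params$n) - params$k_T * x
}

#' Fixed points of the autonomous Tbet equation
#'
#' With no APC engagement the Tbet equation decouples; its steady states are
#' the non-negative roots of
#' `lam_T2 x^n / (lam_T3^n + x^n) = k_T x`. When the bistability condition
#' holds (see [check_bistability()]) there are exactly three: 0 and a high
#' state, both stable, separated by an unstable threshold.
#'
#' Roots are located by a sign-change scan on a fine grid over
#' `[0, 10 lam_T2 / k_T]` refined by bisection; stability is read off the
#' sign of the derivative of the right-hand side at the root.
#'
#' @param params Parameters from [molecular_params()].
#' @param grid_n Number of scan points.
#' @return A tibble with columns `root` (mol/L, ascending) and `stable`.
#' @export
tbet_fixed_points <- function(params = molecular_params(), grid_n = 20000L) {
  f <- function(x) tbet_autonomous(x, params)
  upper <- 10 * params$lam_T2 / params$k_T
  xs <- seq(0, upper, length.out = grid_n)
  fx <- f(xs)
  roots <- 0 # x = 0 is always a root
  for (i in seq_len(grid_n - 1)) {
    if (xs[i] == 0) next
    if (fx[i] == 0) roots <- c(roots, xs[i])
    else if (fx[i] * fx[i + 1] < 0)
      roots <- c(roots, uniroot(f, c(xs[i], xs[i + 1]), tol = 1e-12)$root)
  }
  roots <- sort(unique(roots))
  eps <- max(1e-8, upper * 1e-9)
  stable <- vapply(roots, function(r) {
    (f(r + eps) - f(max(r - eps, 0))) < 0
  }, logical(1))
  tibble::tibble(root = roots, stable = stable)
}

#' Does the Tbet equation satisfy the bistability condition?
#'
#' True when `n > 1` and `lam_T2 (n-1)^((n-1)/n) > n k_T lam_T3`, the
#' necessary and sufficient condition for the autonomous Tbet equation to
#' have three non-negative steady states.
#'
#' @param params Parameters from [molecular_params()].
#' @return `TRUE` or `FALSE`.
#' @export
check_bistability <- function(params = molecular_params()) {
  n <- params$n
  n > 1 && params$lam_T2 * (n - 1)^((n - 1) / n) > n * params$k_T * params$lam_T3
}

#' Asymptotic molecular profile of a resting memory cell
#'
#' Integrates the network with no APC contact, no Fas engagement and no
#' extracellular IL2 (`f_APC = 0`, `H = 0`, `IL2cm = 0`, `Tbcm = 0`, `G = 1`)
#' from a low-Tbet post-effector state until the relative change over an
#' hour falls below `tol`. Under the shipped defaults the profile is
#' Tb = 0, E = 26 and Cas = 9 mol/L.
#'
#' @param params Parameters from [molecular_params()].
#' @param start Starting state; default is a low-Tbet post-effector state.
#' @param tol Relative-change convergence tolerance per hour.
#' @param max_hours Give up (with an error) after this much simulated time.
#' @return A one-row tibble of the steady state.
#' @export
asymptotic_memory_state <- function(params = molecular_params(),
                                    start = molecular_state(R = 10, LR = 5, Tb = 5,
                                                            Fs = 1, Cas = 10, E = 10),
                                    tol = 1e-9, max_hours = 5000) {
  env <- environment_inputs(f_APC = 0, G = 1, H = 0, IL2cm = 0, Tbcm = 0)
  x <- as_mol_matrix(start)[1, ]
  hours <- 0
  repeat {
    nxt <- cpp_step_molecular(matrix(x, 1), as.matrix(env), params, 0.25, 4L)$state[1, ]
    hours <- hours + 1
    delta <- max(abs(nxt - x) / pmax(abs(x), 1))
    x <- nxt
    if (delta < tol) break
    if (hours > max_hours)
      stop("memory state did not converge within ", max_hours,
           " h; last state: ", paste(signif(x, 4), collapse = ", "))
  }
  out <- tibble::as_tibble(as.list(setNames(x, mol_vars)))
  out
}
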