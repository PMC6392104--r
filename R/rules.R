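# Cell-level rules: the division-number-dependent cycle length, stochastic
# uneven partitioning of molecular content (with the polarised asymmetric
# first division), the irreversible differentiation scheme, and apoptosis.

#' Mean cell cycle length after k divisions
#'
#' `c_k = 6 + 28 k^2 / (k^2 + 100)` hours: early divisions are fast (6 h on
#' average) and the mean lengthens towards 34 h with division number.
#'
#' @param k Division count (non-negative integer), vectorised.
#' @return Mean cycle length in hours.
#' @export
cycle_length_mean <- function(k) {
  if (any(k < 0)) stop("k must be >= 0")
  6 + 28 * k^2 / (k^2 + 100)
}

#' Sample cell cycle lengths
#'
#' Drawn at cell birth from `U[c_k - 4, c_k + 4]` with
#' `c_k = 6 + 28 k^2 / (k^2 + 100)`; the first cycle (k = 0) therefore lies
#' in \[2, 10\] hours and every draw is positive.
#'
#' @param k Division count (scalar or vector; recycled against `n`).
#' @param n Number of draws.
#' @return Cycle lengths in hours.
#' @export
sample_cycle_length <- function(k, n = length(k)) {
  ck <- cycle_length_mean(rep_len(k, n))
  runif(n, ck - 4, ck + 4)
}

#' Uneven partitioning of molecular content at division
#'
#' Independently for each of the six proteins, a coefficient
#' `k_i ~ U[1 - m/100, 1]` is drawn; one daughter (chosen by an independent
#' fair coin per protein) inherits `k_i [i]` and the other `(2 - k_i) [i]`.
#' Because daughters have half the mother's volume, the concentrations sum
#' exactly to twice the mother's: molecule number is conserved.
#'
#' @param mother One-row molecular state (see [molecular_state()]).
#' @param m Degree of unevenness in percent (0 to 100); at `m = 10` the most
#'   uneven split is 45/55 percent of the mother's molecules.
#' @return A two-row tibble (daughter 1, daughter 2).
#' @export
partition_concentrations <- function(mother, m = 10) {
  if (m < 0 || m > 100) stop("m must be in [0, 100]")
  x <- as_mol_matrix(mother)[1, ]
  ki <- runif(6, 1 - m / 100, 1)
  first <- runif(6) < 0.5
  d1 <- ifelse(first, ki, 2 - ki) * x
  d2 <- ifelse(first, 2 - ki, ki) * x
  out <- rbind(d1, d2)
  rownames(out) <- NULL
  colnames(out) <- mol_vars
  tibble::as_tibble(out)
}

#' Asymmetric first division after activation
#'
#' The first division of an activated cell is polarised: a coefficient
#' `K ~ U[0.5, 1]` splits Tbet so that the proximal daughter receives
#' `(2 - K) [Tb]` and the distal one `K [Tb]` (Tbet accumulates in the
#' proximal cell; the proximal/distal ratio lies in \[1, 3\]). The other
#' five proteins are partitioned by the ordinary uneven rule.
#'
#' @inheritParams partition_concentrations
#' @return A two-row tibble, row 1 proximal, row 2 distal.
#' @export
asymmetric_first_division <- function(mother, m = 10) {
  x <- as_mol_matrix(mother)[1, ]
  out <- as.matrix(partition_concentrations(mother, m))
  K <- runif(1, 0.5, 1)
  out[1, "Tb"] <- (2 - K) * x["Tb"]
  out[2, "Tb"] <- K * x["Tb"]
  tibble::as_tibble(out)
}

# the irreversible differentiation scheme: allowed transitions and triggers
scheme_order <- c(naive = 1, pre_activated = 2, activated = 3, effector = 4,
                  memory = 5)

#' Apply a differentiation rule
#'
#' Implements the irreversible scheme: a naive (or, on re-stimulation, a
#' memory) cell binding an APC becomes pre-activated; a pre-activated cell
#' whose activated-receptor level reaches `IL2R_th` becomes activated and
#' starts cycling; at division each daughter is typed by its Tbet level
#' against `Tbet_th` (activated below, effector at or above); and a dividing
#' cell whose Eomes exceeds `Eomes_th` converts to memory and stops
#' proliferating.
#'
#' @param type Current cell type (one of [cell_types()] except medium/apc).
#' @param event One of `"apc_contact"`, `"receptor_check"`,
#'   `"division_daughter"`, `"division_check"`.
#' @param state One-row molecular state of the cell being evaluated.
#' @param thresholds A [cd8_thresholds()].
#' @return The resulting cell type (possibly unchanged).
#' @export
apply_differentiation <- function(type, event, state,
                                  thresholds = cd8_thresholds()) {
  if (!type %in% cd8_stages()) stop("not a CD8 T-cell type: ", type)
  x <- as_mol_matrix(state)[1, ]
  new <- switch(event,
    apc_contact = if (type %in% c("naive", "memory")) "pre_activated" else type,
    receptor_check = if (type == "pre_activated" && x["LR"] >= thresholds$IL2R_th)
      "activated" else type,
    division_check = if (type %in% c("activated", "effector") &&
                         x["E"] > thresholds$Eomes_th) "memory" else type,
    division_daughter = if (x["Tb"] >= thresholds$Tbet_th) "effector" else "activated",
    stop("unknown event: ", event)
  )
  # guard the scheme's irreversibility (memory -> pre-activated re-entry is
  # the one sanctioned return edge)
  if (!(type == "memory" && new == "pre_activated") &&
      event != "division_daughter" &&
      scheme_order[new] < scheme_order[type])
    stop("illegal reverse transition ", type, " -> ", new)
  unname(new)
}

#' Apoptosis check
#'
#' A non-naive CD8 T-cell dies as soon as its Caspase concentration reaches
#' `Caspases_th`; naive cells never die. An APC dies when the current time
#' reaches its lifetime, drawn at simulation start from U\[48, 96\] hours.
#'
#' @param type Cell type.
#' @param Cas Caspase concentration (CD8 cells).
#' @param thresholds A [cd8_thresholds()].
#' @param now Current time in hours (APCs).
#' @param apc_death_time The APC's drawn death time in hours.
#' @return `TRUE` if the cell dies.
#' @export
check_apoptosis <- function(type, Cas = 0, thresholds = cd8_thresholds(),
                            now = 0, apc_death_time = Inf) {
  if (type == "apc") return(now >= apc_death_time)
  if (type == "naive") return(FALSE)
  Cas >= thresholds$Caspases_th
}

#' Sample APC lifetimes
#'
#' @param n Number of APCs.
#' @return Lifetimes in hours, uniform on \[48, 96\].
#' @export
sample_apc_lifetime <- function(n = 1) {
  runif(n, 48, 96)
}
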