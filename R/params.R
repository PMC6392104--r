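# Parameter constructors and the shipped calibrated default set.
#
# The published description of this model keeps its numeric parameter table in
# supplementary material; the values shipped here are this package's own
# calibrated defaults. They are constrained so that (a) the Tbet equation is
# bistable with fixed points at 21 and 118 mol/L, (b) the resting memory
# profile is (Tb, E, Cas) = (0, 26, 9) mol/L, and (c) scaled-down simulations
# reproduce the qualitative expansion / contraction / memory-emergence
# dynamics of the response. See the methods vignette for the calibration
# rationale.

#' Cell type levels used throughout the package
#'
#' Integer codes 0 to 6 in the compiled engine map onto these labels, in
#' order: extracellular medium, antigen-presenting cell, then the five CD8
#' T-cell differentiation stages.
#'
#' @return A character vector of the seven lattice cell types.
#' @export
cell_types <- function() {
  c("medium", "apc", "naive", "pre_activated", "activated", "effector", "memory")
}

cd8_stages <- function() cell_types()[3:7]

type_code <- function(type) {
  match(type, cell_types()) - 1L
}

type_label <- function(code) {
  cell_types()[code + 1L]
}

#' Molecular network rate parameters
#'
#' Rates of the six-variable intracellular network: non-activated IL2
#' receptors `R`, activated receptors `LR`, Tbet `Tb`, activated Fas `Fs`,
#' Caspases `Cas` and Eomes `E`. All rates are per hour, concentrations in
#' mol/L. `n` is the dimensionless Hill exponent of the Tbet positive
#' feedback loop.
#'
#' The default set satisfies the bistability condition
#' `n > 1 && lam_T2 * (n - 1)^((n - 1)/n) > n * k_T * lam_T3`
#' and places the positive Tbet fixed points at exactly 21 (unstable) and
#' 118 (stable) mol/L: with `n = 2` the positive roots solve
#' `x^2 - (lam_T2/k_T) x + lam_T3^2 = 0`, so `lam_T2/k_T = 21 + 118` and
#' `lam_T3^2 = 21 * 118`.
#'
#' @param ... Named overrides of individual parameters.
#' @param fas_cap_mode Saturation level of the Fas activation term:
#'   `"saturating"` (default) uses `lam_F / k_F` so that `Fs` stays bounded;
#'   `"product"` uses `lam_F * k_F`.
#' @return A named list of class `"molecular_params"`.
#' @export
molecular_params <- function(..., fas_cap_mode = c("saturating", "product")) {
  p <- list(
    # IL2 receptor module: stable R-LR loop (loop gain < 1 requires
    # lam_R2 < k_e), activation reached ~10 h into APC contact
    lam_R1 = 10, lam_R2 = 0.02, lam_E1 = 0.1, k_R = 0.1,
    mu_IL2_plus = 1, mu_IL2_minus = 0.1, k_e = 0.2,
    # Tbet bistable module: fixed points at 21 and 118 mol/L by construction
    lam_T1 = 4.1, lam_T2 = 13.9, lam_T3 = sqrt(21 * 118), n = 2, k_T = 0.1,
    # Fas activation (saturation level lam_F / k_F = 20)
    mu_F_plus = 0.002, mu_F_minus = 0.05, lam_F = 2, k_F = 0.1,
    # Caspases: effector program autonomously lethal (lam_c1 / k_c = 25
    # above Caspases_th = 19) but Eomes-gated so that the resting memory
    # equilibrium is lam_c1 / (k_c (1 + 26 lam_E2)) = 9 mol/L
    lam_c1 = 0.5, lam_c2 = 0.001, lam_c3 = 0.5, lam_c4 = 0.005,
    lam_E2 = 0.0684, k_c = 0.02,
    # Eomes: fast module (memory level lam_E4 / k_E = 26 mol/L), strongly
    # inhibited by Tbet so protection reaches only low-Tbet cells
    lam_E3 = 0.05, lam_E4 = 2.6, lam_E5 = 1, lam_E6 = 30, lam_E7 = 0.3,
    k_E = 0.1
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown molecular parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  bad <- vapply(p, function(x) !is.numeric(x) || length(x) != 1 || x <= 0, logical(1))
  if (any(bad)) stop("molecular parameters must be positive scalars: ",
                     paste(names(p)[bad], collapse = ", "))
  p$fas_cap_mode <- match.arg(fas_cap_mode)
  structure(p, class = c("molecular_params", "list"))
}

#' IL2 field parameters
#'
#' Diffusion, decay and secretion-term parameters of the extracellular IL2
#' reaction-diffusion equation. `D` is in lattice-node^2 per hour; one node is
#' 4 um, so `D` in um^2/h is `16 * D`. `delta` is the decay rate per hour.
#'
#' @param D Diffusion coefficient (node^2/h).
#' @param delta IL2 decay rate (/h).
#' @param lam_R3,lam_R4 Michaelian secretion driven by activated receptors.
#' @param lam_1 Secretion driven by APC engagement.
#' @param lam_T4 Tbet inhibition of secretion.
#' @return A named list of class `"field_params"`.
#' @export
field_params <- function(D = 10, delta = 0.3, lam_R3 = 2, lam_R4 = 5,
                         lam_1 = 3, lam_T4 = 0.05) {
  p <- list(D = D, delta = delta, lam_R3 = lam_R3, lam_R4 = lam_R4,
            lam_1 = lam_1, lam_T4 = lam_T4)
  bad <- vapply(p, function(x) !is.numeric(x) || length(x) != 1 || x < 0, logical(1))
  if (any(bad)) stop("field parameters must be non-negative scalars")
  structure(p, class = c("field_params", "list"))
}

#' Cellular Potts model configuration
#'
#' Contact energies, area/perimeter constraints, Boltzmann temperature and
#' motility weights of the lattice model. Target areas are in nodes and
#' target perimeters in micrometres (one node edge = 4 um); a CD8 T-cell
#' targets 9 nodes (144 um^2) and a 48 um perimeter, which a 3 x 3 square
#' satisfies exactly. APCs target 140 nodes with no perimeter constraint.
#'
#' The default contact-energy table encodes the adhesion story of the
#' differentiation scheme: pre-activated cells adhere strongly to APCs
#' (lowest J), activated and effector cells detach (high J), and naive and
#' memory cells adhere just enough to bind an APC and enter the scheme.
#'
#' @param J Symmetric 7 x 7 contact-energy matrix over [cell_types()].
#' @param lam_area,lam_pm Weights of the area and perimeter constraints.
#' @param temperature Boltzmann temperature of the copy-attempt acceptance.
#' @param A Target areas (nodes) per type; `NA` = unconstrained.
#' @param P Target perimeters (um) per type; `NA` = unconstrained.
#' @param v Motility weight per type (0 for static medium and APCs).
#' @param theta_interval MCS between refreshes of each cell's privileged
#'   direction angle.
#' @return A list of class `"potts_config"`.
#' @export
potts_config <- function(J = NULL, lam_area = 12, lam_pm = 0.2, temperature = 15,
                         A = c(NA, 140, 9, 9, 9, 9, 9),
                         P = c(NA, NA, 48, 48, 48, 48, 48),
                         v = c(0, 0, 40, 5, 20, 20, 30),
                         theta_interval = 40) {
  tt <- cell_types()
  if (is.null(J)) {
    J <- matrix(11, 7, 7, dimnames = list(tt, tt))
    J["medium", ] <- J[, "medium"] <- 16
    J["medium", "medium"] <- 0
    J["apc", "apc"] <- 14
    J["apc", "naive"] <- J["naive", "apc"] <- 8
    J["apc", "pre_activated"] <- J["pre_activated", "apc"] <- 2
    J["apc", "activated"] <- J["activated", "apc"] <- 30
    J["apc", "effector"] <- J["effector", "apc"] <- 30
    J["apc", "memory"] <- J["memory", "apc"] <- 8
  }
  if (!is.matrix(J) || any(dim(J) != 7) || !isTRUE(all.equal(J, t(J))))
    stop("J must be a symmetric 7 x 7 matrix over the cell types")
  if (lam_area < 0 || lam_pm < 0 || temperature <= 0)
    stop("lam_area, lam_pm must be >= 0 and temperature > 0")
  structure(list(J = J, lam_area = lam_area, lam_pm = lam_pm,
                 temperature = temperature,
                 A = as.numeric(A), P = as.numeric(P), v = as.numeric(v),
                 theta_interval = as.integer(theta_interval)),
            class = c("potts_config", "list"))
}

#' Differentiation, division and apoptosis thresholds
#'
#' @param IL2R_th Activated-receptor concentration at which a pre-activated
#'   cell becomes activated and starts cycling (mol/L).
#' @param Tbet_th Tbet level separating activated from effector daughters at
#'   division (mol/L).
#' @param Eomes_th Eomes level above which a dividing cell converts to the
#'   memory state instead (mol/L).
#' @param Caspases_th Caspase level triggering apoptosis (mol/L); never
#'   applied to naive cells.
#' @param m Degree of unevenness of molecular partitioning at division, in
#'   percent: each protein's inherited fraction is drawn from
#'   U\[(100 - m)/2, 50\] percent for one daughter (the other receives the
#'   complement).
#' @param memory_divides If `TRUE`, a dividing cell above `Eomes_th` divides
#'   and both daughters become memory; the default converts the mother
#'   without division.
#' @return A list of class `"cd8_thresholds"`.
#' @export
cd8_thresholds <- function(IL2R_th = 30, Tbet_th = 60, Eomes_th = 16,
                           Caspases_th = 19, m = 10, memory_divides = FALSE) {
  if (m < 0 || m > 100) stop("m must be in [0, 100]")
  if (any(c(IL2R_th, Tbet_th, Eomes_th, Caspases_th) <= 0))
    stop("all thresholds must be positive")
  structure(list(IL2R_th = IL2R_th, Tbet_th = Tbet_th, Eomes_th = Eomes_th,
                 Caspases_th = Caspases_th, m = m,
                 memory_divides = isTRUE(memory_divides)),
            class = c("cd8_thresholds", "list"))
}
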