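# The Cellular Potts layer: Hamiltonian, motility bias, the Monte Carlo step
# and lattice utilities. The heavy lifting is compiled; these wrappers take
# and return ordinary R matrices and tibbles.

check_cells_df <- function(cells) {
  cells <- tibble::as_tibble(cells)
  if (!all(c("id", "type") %in% names(cells)))
    stop("cells must have columns id and type")
  if (!all(cells$type %in% cell_types()))
    stop("unknown cell type; see cell_types()")
  if (!"theta" %in% names(cells)) cells$theta <- 0
  if (!"v" %in% names(cells)) cells$v <- 0
  cells
}

#' Energy of a lattice configuration
#'
#' The Potts Hamiltonian: perimeter and area penalties over all non-medium
#' cells plus heterotypic contact energies over first-order neighbour pairs.
#' Perimeters are measured as boundary node-edges times 4 um, so a 3 x 3
#' cell has perimeter 48 um. Same-cell neighbour pairs contribute no contact
#' energy.
#'
#' @param sigma Integer lattice of cell indices (0 = medium), periodic.
#' @param cells Data frame with columns `id` and `type` (one of
#'   [cell_types()]).
#' @param config A [potts_config()].
#' @return The dimensionless energy.
#' @export
hamiltonian <- function(sigma, cells, config = potts_config()) {
  cells <- check_cells_df(cells)
  cpp_hamiltonian(sigma, as.integer(cells$id), type_code(cells$type), config)
}

#' Motility energy of a copy attempt
#'
#' The dot product of the source cell's unit heading
#' `(cos theta, sin theta)` with the copy direction `x_g - x_s`, scaled by
#' the cell's motility weight `v`. Copies aligned with the privileged
#' direction gain energy and are accepted more readily.
#'
#' @param v Motility weight of the source cell (0 for medium).
#' @param theta Privileged direction angle (radians).
#' @param dx,dy Copy direction components.
#' @return The motility energy contribution.
#' @export
delta_motility <- function(v, theta, dx, dy) {
  v * (cos(theta) * dx + sin(theta) * dy)
}

#' Metropolis acceptance of energy changes
#'
#' Accepts an energy-decreasing move outright and an energy-increasing one
#' with Boltzmann probability `exp(-dE / temperature)`. This is the decision
#' rule used for every copy attempt in the engine, exposed for direct
#' statistical checks.
#'
#' @param dE Energy increases (net of the motility bias); vectorised.
#' @param temperature Boltzmann temperature.
#' @return A logical vector of acceptances (stochastic for `dE > 0`).
#' @export
metropolis_accept <- function(dE, temperature) {
  as.logical(cpp_metropolis_accept(as.numeric(dE), temperature))
}

#' One (or more) Monte Carlo steps of the Potts model
#'
#' Performs exactly `N = 3 S` copy attempts per MCS on an `L x L` lattice of
#' `S` nodes: each attempt picks a random source node and a random
#' first-order neighbour as target, evaluates the local energy change of
#' copying the source index onto the target (plus the motility bias), and
#' accepts by the Metropolis rule. Area and perimeter bookkeeping is
#' incremental; the returned `hamiltonian` is the incrementally accumulated
#' energy after all attempts.
#'
#' @inheritParams hamiltonian
#' @param cells Data frame with columns `id`, `type` and optionally `theta`
#'   and `v` (privileged angle and motility weight, defaulting to 0).
#' @param n_mcs Number of Monte Carlo steps to run.
#' @return A list with `sigma` (updated lattice), `attempts`, `accepted` and
#'   `hamiltonian`.
#' @export
monte_carlo_step <- function(sigma, cells, config = potts_config(), n_mcs = 1L) {
  cells <- check_cells_df(cells)
  res <- cpp_monte_carlo_step(sigma, as.integer(cells$id), type_code(cells$type),
                              as.numeric(cells$theta), as.numeric(cells$v),
                              config, as.integer(n_mcs))
  res
}

#' Cell-cell contact map
#'
#' Two cells are in contact iff some node of one is a first-order neighbour
#' of a node of the other. Returns each unordered pair once.
#'
#' @param sigma Integer lattice of cell indices (0 = medium), periodic.
#' @param cells Optional data frame with `id` and `type`; when supplied the
#'   types of both partners are joined on.
#' @return A tibble with columns `id1`, `id2` (and `type1`, `type2`).
#' @export
contact_map <- function(sigma, cells = NULL) {
  prs <- cpp_contact_pairs(sigma)
  out <- tibble::tibble(id1 = prs[, 1], id2 = prs[, 2])
  if (!is.null(cells)) {
    cells <- check_cells_df(cells)
    lk <- setNames(cells$type, cells$id)
    out$type1 <- unname(lk[as.character(out$id1)])
    out$type2 <- unname(lk[as.character(out$id2)])
  }
  out
}

#' Split a cell into two connected daughters
#'
#' Partitions the cell's nodes into two connected sets of as near as
#' possible equal size by growing two regions from the extreme nodes along
#' the principal axis of the cell's node coordinates (the spatial
#' realisation of cell division).
#'
#' @param sigma Integer lattice of cell indices.
#' @param cell_id Cell to divide (area must be at least 2 nodes).
#' @param new_id Index assigned to the second daughter.
#' @return A list with the updated `sigma` and the two daughter areas `n1`,
#'   `n2`.
#' @export
split_cell <- function(sigma, cell_id, new_id = max(sigma) + 1L) {
  cpp_split_cell(sigma, as.integer(cell_id), as.integer(new_id))
}

#' Boundary nodes of a cell
#'
#' Nodes of the cell with at least one first-order neighbour outside it.
#'
#' @param sigma Integer lattice of cell indices.
#' @param cell_id Cell index.
#' @return A two-column matrix of (row, col) indices.
#' @export
boundary_nodes <- function(sigma, cell_id) {
  cpp_boundary_nodes(sigma, as.integer(cell_id))
}
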