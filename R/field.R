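# Extracellular IL2: secretion by engaged CD8 T-cells, isotropic diffusion on
# the Potts lattice with periodic boundaries, and first-order decay.

#' Create an IL2 field
#'
#' A lattice-aligned extracellular IL2 concentration grid. The grid shape
#' equals the Potts lattice shape and wraps periodically in both axes.
#'
#' @param L Lattice side (nodes).
#' @param params Field parameters from [field_params()].
#' @param init Initial concentration: a scalar or an `L x L` matrix.
#' @return A list of class `"il2_field"` with elements `grid` and `params`.
#' @export
il2_field <- function(L, params = field_params(), init = 0) {
  grid <- if (is.matrix(init)) init else matrix(init, L, L)
  if (nrow(grid) != L || ncol(grid) != L) stop("init must be scalar or L x L")
  if (any(grid < 0)) stop("IL2 concentrations must be non-negative")
  structure(list(grid = grid, params = params), class = "il2_field")
}

#' Per-cell IL2 secretion rate
#'
#' `(lam_R3 LR / (lam_R4 + LR) + lam_1 f_APC) / (1 + lam_T4 Tb)` in mol/L/h:
#' Michaelian drive by activated receptors plus an APC-engagement term, both
#' inhibited by Tbet. Naive cells and APCs do not secrete (the engine never
#' calls this for them; standalone calls return the formula value).
#'
#' @param state One-row molecular state (see [molecular_state()]).
#' @param f_APC Number of APCs in contact.
#' @param params Field parameters from [field_params()].
#' @return Secretion rate (mol/L/h).
#' @export
secretion_rate <- function(state, f_APC = 0, params = field_params()) {
  m <- as_mol_matrix(state)
  vapply(seq_len(nrow(m)), function(r) cpp_secretion_rate(m[r, ], f_APC, params),
         numeric(1))
}

#' Advance the IL2 field by a time step
#'
#' Forward-time centred-space update with the 4-neighbour Laplacian and
#' periodic wrap; secretion is added at source nodes and decay applied. The
#' step is subcycled internally so that `D dt_sub / dx^2 <= 1/4`.
#'
#' @param field An [il2_field()].
#' @param sources `L x L` matrix of per-node secretion rates (mol/L/h).
#' @param dt Time step in hours.
#' @return The updated `il2_field`.
#' @export
step_field <- function(field, sources = NULL, dt = 1 / 60) {
  L <- nrow(field$grid)
  if (is.null(sources)) sources <- matrix(0, L, L)
  field$grid <- cpp_field_step(field$grid, sources, field$params$D,
                               field$params$delta, dt)
  field
}

#' IL2 concentration at a cell's membrane
#'
#' The sum of the field over the cell's boundary nodes (nodes of the cell
#' with at least one first-order neighbour outside the cell). Two
#' alternative readings are available: summing over all of the cell's nodes,
#' or over adjacent medium nodes.
#'
#' @param field An [il2_field()].
#' @param sigma Integer lattice of cell indices (0 = medium).
#' @param cell_id The cell index to evaluate.
#' @param mode Which nodes to sum over: `"boundary"` (default), `"all"`, or
#'   `"adjacent"`.
#' @return The summed concentration (mol/L).
#' @export
il2_at_membrane <- function(field, sigma, cell_id,
                            mode = c("boundary", "all", "adjacent")) {
  mode <- match.arg(mode)
  if (!any(sigma == cell_id)) stop("cell ", cell_id, " occupies no node")
  L <- nrow(sigma)
  if (mode == "all") return(sum(field$grid[sigma == cell_id]))
  bn <- cpp_boundary_nodes(sigma, cell_id)
  if (mode == "boundary")
    return(sum(field$grid[cbind(bn[, 1], bn[, 2])]))
  # adjacent: medium neighbours of the cell's boundary nodes, each node once
  wrap <- function(i) ((i - 1) %% L) + 1
  adj <- unique(do.call(rbind, lapply(seq_len(nrow(bn)), function(k) {
    i <- bn[k, 1]; j <- bn[k, 2]
    rbind(c(wrap(i - 1), j), c(wrap(i + 1), j), c(i, wrap(j - 1)), c(i, wrap(j + 1)))
  })))
  adj <- adj[sigma[adj] != cell_id, , drop = FALSE]
  adj <- unique(adj)
  sum(field$grid[adj])
}
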