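# Shared test fixtures and independent oracles. Every oracle here is written
# from the model definitions directly (plain R, no calls into the package's
# compiled paths) so that implementation and check stay independent.

# term-by-term right-hand side of the six molecular equations
oracle_rhs <- function(x, e, p) {
  fcap <- if (identical(p$fas_cap_mode, "product")) p$lam_F * p$k_F else p$lam_F / p$k_F
  c(
    R  = p$lam_R1 * e[["f_APC"]] + (p$mu_IL2_minus + p$lam_R2) * x[["LR"]] +
         p$lam_E1 * x[["E"]] - (p$mu_IL2_plus * e[["IL2cm"]] + p$k_R) * x[["R"]],
    LR = p$mu_IL2_plus * e[["IL2cm"]] * x[["R"]] - p$mu_IL2_minus * x[["LR"]] -
         p$k_e * x[["LR"]],
    Tb = p$lam_T1 * e[["f_APC"]] +
         p$lam_T2 * x[["Tb"]]^p$n / (p$lam_T3^p$n + x[["Tb"]]^p$n) -
         p$k_T * x[["Tb"]],
    Fs = e[["H"]] * p$mu_F_plus * e[["Tbcm"]] * (fcap - x[["Fs"]]) -
         p$mu_F_minus * x[["Fs"]] - p$k_F * x[["Fs"]],
    Cas = e[["G"]] * p$lam_c1 / (1 + p$lam_c2 * x[["LR"]]) /
          (1 + p$lam_c3 * e[["f_APC"]]) / (1 + p$lam_E2 * x[["E"]]) +
          p$lam_c4 * x[["Fs"]] - p$k_c * x[["Cas"]],
    E  = 1 / (1 + p$lam_E5 * e[["f_APC"]]) *
         (p$lam_E3 * x[["LR"]] / (p$lam_E6 + x[["LR"]]) +
          e[["G"]] * p$lam_E4 / (1 + p$lam_E7 * x[["Tb"]])) -
         p$k_E * x[["E"]]
  )
}

# grid sign-change scan for the roots of the autonomous Tbet equation
oracle_tbet_roots <- function(p, n_grid = 40000) {
  f <- function(x) p$lam_T2 * x^p$n / (p$lam_T3^p$n + x^p$n) - p$k_T * x
  xs <- seq(0, 10 * p$lam_T2 / p$k_T, length.out = n_grid)
  fx <- f(xs)
  roots <- 0
  for (i in seq_len(n_grid - 1)) {
    if (xs[i] == 0) next
    if (fx[i] * fx[i + 1] < 0)
      roots <- c(roots, uniroot(f, c(xs[i], xs[i + 1]), tol = 1e-12)$root)
  }
  sort(roots)
}

wrap_idx <- function(i, L) ((i - 1) %% L) + 1

shift_mat <- function(m, di, dj) {
  L <- nrow(m)
  m[wrap_idx(seq_len(L) + di, L), wrap_idx(seq_len(L) + dj, L)]
}

# vectorised brute-force Hamiltonian on a periodic lattice
oracle_hamiltonian <- function(sigma, cells, cfg) {
  tt <- cell_types()
  typ <- setNames(cells$type, as.character(cells$id))
  tidx <- matrix(1L, nrow(sigma), ncol(sigma)) # medium = index 1
  nz <- sigma != 0
  tidx[nz] <- match(typ[as.character(sigma[nz])], tt)
  E <- 0
  for (sh in list(c(1, 0), c(0, 1))) { # each unordered pair once
    s2 <- shift_mat(sigma, sh[1], sh[2])
    t2 <- shift_mat(tidx, sh[1], sh[2])
    mm <- sigma != s2
    E <- E + sum(cfg$J[cbind(tidx[mm], t2[mm])])
  }
  mism <- Reduce(`+`, lapply(list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)),
                             function(sh) sigma != shift_mat(sigma, sh[1], sh[2])))
  for (id in setdiff(unique(as.vector(sigma)), 0)) {
    ti <- match(typ[[as.character(id)]], tt)
    area <- sum(sigma == id)
    edges <- sum(mism[sigma == id])
    if (!is.na(cfg$A[ti])) E <- E + cfg$lam_area * (area - cfg$A[ti])^2
    if (!is.na(cfg$P[ti])) E <- E + cfg$lam_pm * (4 * edges - cfg$P[ti])^2
  }
  E
}

# brute-force all-pairs contact scan
oracle_contacts <- function(sigma) {
  L <- nrow(sigma)
  prs <- list()
  for (i in seq_len(L)) for (j in seq_len(L)) {
    a <- sigma[i, j]
    if (a == 0) next
    for (nb in list(c(wrap_idx(i + 1, L), j), c(i, wrap_idx(j + 1, L)))) {
      b <- sigma[nb[1], nb[2]]
      if (b != 0 && b != a) prs[[length(prs) + 1]] <- c(min(a, b), max(a, b))
    }
  }
  if (!length(prs)) return(matrix(integer(), 0, 2))
  unique(do.call(rbind, prs))
}

# drop a random blob of cells on a lattice; returns sigma + cells table
random_lattice <- function(L = 20, n_cells = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sigma <- matrix(0L, L, L)
  for (id in seq_len(n_cells)) {
    i0 <- sample(L, 1); j0 <- sample(L, 1)
    h <- sample(2:4, 1); w <- sample(2:4, 1)
    sigma[wrap_idx(i0:(i0 + h - 1), L), wrap_idx(j0:(j0 + w - 1), L)] <- id
  }
  present <- setdiff(unique(as.vector(sigma)), 0)
  cells <- tibble::tibble(
    id = present,
    type = sample(cd8_stages(), length(present), replace = TRUE)
  )
  list(sigma = sigma, cells = cells)
}

# connected components of a node set under 4-neighbour periodic adjacency
oracle_connected <- function(sigma, id) {
  L <- nrow(sigma)
  nodes <- which(sigma == id, arr.ind = TRUE)
  if (nrow(nodes) == 0) return(TRUE)
  key <- function(i, j) paste(i, j)
  todo <- key(nodes[1, 1], nodes[1, 2])
  all_keys <- apply(nodes, 1, function(r) key(r[1], r[2]))
  seen <- character()
  while (length(todo)) {
    k <- todo[1]; todo <- todo[-1]
    if (k %in% seen) next
    seen <- c(seen, k)
    ij <- as.integer(strsplit(k, " ")[[1]])
    for (nb in list(c(wrap_idx(ij[1] + 1, L), ij[2]), c(wrap_idx(ij[1] - 1, L), ij[2]),
                    c(ij[1], wrap_idx(ij[2] + 1, L)), c(ij[1], wrap_idx(ij[2] - 1, L)))) {
      nk <- key(nb[1], nb[2])
      if (nk %in% all_keys && !(nk %in% seen)) todo <- c(todo, nk)
    }
  }
  length(seen) == length(all_keys)
}

# count snapshot-to-snapshot type transitions that reverse the scheme.
# The one sanctioned return path is memory -> pre-activated on APC
# restimulation; with coarse snapshot cadence the memory state in between
# may be visible only as a memory_conversion event, and by the following
# snapshot the restimulated cell may already have progressed again.
count_reverse_transitions <- function(sim) {
  ord <- c(naive = 1, pre_activated = 2, activated = 3, effector = 4, memory = 5)
  cells <- sim$cells[order(sim$cells$id, sim$cells$mcs), ]
  conv <- sim$events[sim$events$event == "memory_conversion", ]
  bad <- 0
  for (id in unique(cells$id)) {
    sel <- cells$id == id
    o <- unname(ord[cells$type[sel]])
    ms <- cells$mcs[sel]
    for (i in which(diff(o) < 0)) {
      went_memory <- o[i] == 5 ||
        any(conv$id == id & conv$mcs >= ms[i] & conv$mcs <= ms[i + 1])
      if (!(went_memory && o[i + 1] >= 2)) bad <- bad + 1
    }
  }
  bad
}

# scaled-down primary / secondary runs, computed once and reused across tests
.run_cache <- new.env(parent = emptyenv())

ci_primary_run <- function() {
  if (is.null(.run_cache$primary)) {
    set.seed(1)
    .run_cache$primary <- run_primary(sim_config("ci"))
  }
  .run_cache$primary
}

ci_secondary_run <- function() {
  if (is.null(.run_cache$secondary)) {
    set.seed(1)
    .run_cache$secondary <- run_secondary(sim_config("ci"))
  }
  .run_cache$secondary
}
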