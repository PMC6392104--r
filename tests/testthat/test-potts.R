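# The Cellular Potts engine: Hamiltonian, Metropolis rule, MCS bookkeeping,
# contacts and cell splitting.

test_that("an all-medium lattice has zero energy", {
  sigma <- matrix(0L, 20, 20)
  cells <- tibble::tibble(id = integer(), type = character())
  expect_equal(hamiltonian(sigma, cells), 0)
})

test_that("a single 3x3 CD8 cell satisfies its constraints exactly", {
  sigma <- matrix(0L, 20, 20)
  sigma[5:7, 5:7] <- 1L
  cells <- tibble::tibble(id = 1L, type = "naive")
  cfg <- potts_config()
  # area 9 = target, perimeter 12 edges x 4 um = 48 um = target:
  # only the 12 heterotypic boundary edges contribute, at J(naive, medium)
  expect_equal(hamiltonian(sigma, cells, cfg), 12 * cfg$J["naive", "medium"])
})

test_that("Hamiltonian equals the brute-force oracle on 100 random 20x20 lattices", {
  set.seed(404)
  cfg <- potts_config()
  for (rep in 1:100) {
    rl <- random_lattice(L = 20, n_cells = sample(3:7, 1))
    expect_equal(hamiltonian(rl$sigma, rl$cells, cfg),
                 oracle_hamiltonian(rl$sigma, rl$cells, cfg),
                 tolerance = 1e-9)
  }
})

test_that("motility energy is the scaled dot product with the heading", {
  expect_equal(delta_motility(0, 1.2, 1, 0), 0)
  expect_equal(delta_motility(5, 0, 1, 0), 5)            # aligned
  expect_equal(delta_motility(5, pi / 2, 1, 0), 0, tolerance = 1e-12) # perpendicular
  expect_equal(delta_motility(5, pi, 1, 0), -5)          # anti-aligned
})

test_that("Metropolis acceptance frequency matches exp(-dE/T) within 3 SE", {
  temperature <- 15
  for (dE in c(5, 15, 40)) {
    set.seed(dE)
    n <- 1e5
    p <- exp(-dE / temperature)
    acc <- mean(metropolis_accept(rep(dE, n), temperature))
    expect_lt(abs(acc - p), 3 * sqrt(p * (1 - p) / n))
  }
  # energy-decreasing moves are always accepted; T -> 0 rejects increases
  expect_true(all(metropolis_accept(rep(-1, 100), temperature)))
  set.seed(1)
  expect_true(!any(metropolis_accept(rep(5, 1e4), 1e-3)))
})

test_that("one MCS performs exactly N = 3 S attempts (67,500 on the full lattice)", {
  sigma <- matrix(0L, 150, 150)
  sigma[10:12, 10:12] <- 1L
  cells <- tibble::tibble(id = 1L, type = "naive")
  set.seed(5)
  res <- monte_carlo_step(sigma, cells, n_mcs = 1L)
  expect_equal(res$attempts, 3 * 150 * 150)
  expect_equal(res$attempts, 67500)
})

test_that("incremental energy bookkeeping matches a from-scratch recomputation", {
  set.seed(505)
  cfg <- potts_config()
  for (rep in 1:5) {
    rl <- random_lattice(L = 20, n_cells = 5)
    rl$cells$theta <- runif(nrow(rl$cells), 0, 2 * pi)
    rl$cells$v <- 20
    res <- monte_carlo_step(rl$sigma, rl$cells, cfg, n_mcs = 3L)
    expect_equal(res$hamiltonian, hamiltonian(res$sigma, rl$cells, cfg),
                 tolerance = 1e-9)
    # node conservation: lattice size unchanged, every index either live or medium
    expect_equal(length(res$sigma), 400)
    expect_true(all(res$sigma %in% c(0L, rl$cells$id)))
  }
})

test_that("cells never vanish during Monte Carlo steps", {
  set.seed(606)
  rl <- random_lattice(L = 20, n_cells = 6)
  res <- monte_carlo_step(rl$sigma, rl$cells, potts_config(), n_mcs = 20L)
  for (id in rl$cells$id) expect_gte(sum(res$sigma == id), 1)
})

test_that("contact map matches the brute-force neighbour scan on random lattices", {
  set.seed(707)
  for (rep in 1:20) {
    rl <- random_lattice(L = 30, n_cells = sample(4:9, 1))
    got <- contact_map(rl$sigma)
    exp_pairs <- oracle_contacts(rl$sigma)
    got_m <- matrix(as.integer(as.matrix(got[order(got$id1, got$id2),
                                             c("id1", "id2")])), ncol = 2)
    exp_m <- matrix(as.integer(exp_pairs[order(exp_pairs[, 1], exp_pairs[, 2]), ,
                                         drop = FALSE]), ncol = 2)
    expect_equal(got_m, exp_m)
  }
})

test_that("separated cells are not in contact; abutting cells are", {
  sigma <- matrix(0L, 20, 20)
  sigma[3:5, 3:5] <- 1L
  sigma[3:5, 7:9] <- 2L   # one medium column between
  expect_equal(nrow(contact_map(sigma)), 0)
  sigma[3:5, 6] <- 2L     # now abutting
  cm <- contact_map(sigma, tibble::tibble(id = 1:2, type = c("naive", "apc")))
  expect_equal(nrow(cm), 1)
  expect_equal(cm$type2[1], "apc")
})

test_that("splitting bisects into two connected near-equal daughters", {
  sigma <- matrix(0L, 12, 12)
  sigma[4:6, 4:6] <- 1L
  res <- split_cell(sigma, 1, 2)
  expect_equal(sort(c(res$n1, res$n2)), c(4, 5))
  expect_true(oracle_connected(res$sigma, 1))
  expect_true(oracle_connected(res$sigma, 2))
  # 1x2 domino -> two single nodes
  sigma2 <- matrix(0L, 8, 8)
  sigma2[3, 4:5] <- 1L
  res2 <- split_cell(sigma2, 1, 2)
  expect_equal(c(res2$n1, res2$n2), c(1, 1))
  expect_error(split_cell(matrix(c(1L, rep(0L, 35)), 6, 6), 1, 2), "2 nodes")
})

test_that("split conserves nodes and stays connected for random grown shapes", {
  set.seed(808)
  for (rep in 1:30) {
    L <- 16
    sigma <- matrix(0L, L, L)
    i <- sample(L, 1); j <- sample(L, 1)
    sigma[i, j] <- 1L
    target <- sample(6:20, 1)
    while (sum(sigma == 1) < target) { # random connected growth
      nodes <- which(sigma == 1, arr.ind = TRUE)
      r <- nodes[sample(nrow(nodes), 1), ]
      d <- sample(list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)), 1)[[1]]
      sigma[wrap_idx(r[1] + d[1], L), wrap_idx(r[2] + d[2], L)] <- 1L
    }
    m <- sum(sigma == 1)
    res <- split_cell(sigma, 1, 2)
    expect_equal(res$n1 + res$n2, m)
    expect_true(oracle_connected(res$sigma, 1))
    expect_true(oracle_connected(res$sigma, 2))
    expect_lte(abs(res$n1 - res$n2), max(1, ceiling(0.34 * m)))
  }
})

test_that("with a strong area constraint and low temperature areas settle on target", {
  sigma <- matrix(0L, 24, 24)
  sigma[2:6, 2:6] <- 1L    # area 25, target 9
  sigma[12:13, 12:13] <- 2L # area 4, target 9
  cells <- tibble::tibble(id = 1:2, type = "activated")
  cfg <- potts_config(lam_area = 50, lam_pm = 0.2, temperature = 2,
                      v = rep(0, 7))
  set.seed(909)
  res <- monte_carlo_step(sigma, cells, cfg, n_mcs = 500L)
  expect_lte(abs(sum(res$sigma == 1) - 9), 1)
  expect_lte(abs(sum(res$sigma == 2) - 9), 1)
})
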