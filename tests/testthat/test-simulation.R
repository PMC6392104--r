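# The coupled simulation: reproducibility, bookkeeping, and the biological
# course of the scaled-down primary and secondary responses.

test_that("without APCs no cell ever leaves the naive state", {
  set.seed(10)
  cfg <- sim_config("ci", L = 40, n_mcs = 500, n_naive = 8, n_apc = 0)
  s <- run_primary(cfg)
  expect_true(all(s$population$naive == 8))
  expect_true(all(s$population$total_cd8 == 8))
  expect_equal(nrow(s$events), 0)
  # naive cells stay at the all-zero molecular state
  expect_true(all(as.matrix(s$cells[, c("R", "LR", "Tb", "Fs", "Cas", "E")]) == 0))
})

test_that("identical seeds give bit-identical simulations", {
  cfg <- sim_config("ci", L = 40, n_mcs = 600, n_naive = 5, n_apc = 1)
  set.seed(77); a <- run_primary(cfg)
  set.seed(77); b <- run_primary(cfg)
  expect_identical(a$population, b$population)
  expect_identical(a$cells, b$cells)
  expect_identical(a$events, b$events)
  expect_identical(a$final_sigma, b$final_sigma)
  expect_identical(a$final_field, b$final_field)
  set.seed(78); c <- run_primary(cfg)
  expect_false(identical(a$final_sigma, c$final_sigma))
})

test_that("day bookkeeping maps MCS 5760 to day 8 post-infection", {
  set.seed(12)
  cfg <- sim_config("ci", L = 40, n_mcs = 5760, n_naive = 2, n_apc = 0,
                    snapshot_every = 1440L)
  s <- run_primary(cfg)
  expect_equal(s$population$day, 4 + s$population$mcs / 1440)
  expect_equal(s$population$day[s$population$mcs == 5760], 8)
})

test_that("an empty starting population terminates with the extinction flag", {
  set.seed(13)
  cfg <- sim_config("ci", L = 40, n_mcs = 100, n_naive = 0, n_apc = 1)
  s <- run_primary(cfg)
  expect_true(s$stats$extinct)
})

test_that("node counts are conserved on the final lattice", {
  s <- ci_primary_run()
  live_area <- sum(s$final_cells$area)
  expect_equal(sum(s$final_sigma != 0), live_area)
  expect_equal(live_area + sum(s$final_sigma == 0), s$config$L^2)
  # every live cell owns at least one node, and every lattice index is live
  expect_true(all(s$final_cells$area >= 1))
  expect_true(all(setdiff(unique(as.vector(s$final_sigma)), 0L) %in% s$final_cells$id))
})

test_that("type transitions never reverse along the differentiation scheme", {
  s <- ci_primary_run()
  expect_equal(count_reverse_transitions(s), 0)
})

test_that("molecular snapshots stay non-negative and finite over a full run", {
  s <- ci_primary_run()
  m <- as.matrix(s$cells[, c("R", "LR", "Tb", "Fs", "Cas", "E")])
  expect_true(all(is.finite(m)))
  expect_true(all(m >= 0))
})

test_that("the primary response expands, peaks, contracts and leaves memory", {
  s <- ci_primary_run()
  g <- glance(s)
  pop <- s$population
  expect_gt(g$peak_size, 5 * s$config$n_naive)      # clonal expansion happened
  expect_lt(g$peak_day, max(pop$day))               # peak strictly inside the run
  expect_lt(g$final_size, g$peak_size)              # contraction after the peak
  expect_gt(g$final_memory, 0)                      # a memory pool remains
  # memory emerges after the peak: no memory cells at the peak snapshot
  mem_at_peak <- pop$memory[which.max(pop$total_cd8)]
  expect_lt(mem_at_peak, 0.1 * g$final_memory + 1)
  expect_gt(utils::tail(pop$memory, 1), 0.5 * utils::tail(pop$total_cd8, 1))
})

test_that("naive and pre-activated cells are a small minority by day 7", {
  s <- ci_primary_run()
  pop <- s$population
  i7 <- which(pop$day >= 7)[1]
  frac <- (pop$naive[i7] + pop$pre_activated[i7]) / pop$total_cd8[i7]
  expect_lt(frac, 0.10)
})

test_that("the ranked Tbet profile is bimodal late with antagonistic Eomes/Caspases", {
  s <- ci_primary_run()
  pr <- tbet_profile(s)  # last recorded snapshot
  expect_equal(attr(pr, "tb_unstable"), 21, tolerance = 1e-6)
  expect_equal(pr$Tb, sort(pr$Tb))
  # trough between the modes: almost no cell near the unstable point
  expect_lt(attr(pr, "n_trough") / nrow(pr), 0.05)
  expect_gt(attr(pr, "n_below"), 0)
  # high-Tbet cells carry high Caspases and low Eomes
  if (attr(pr, "n_above") >= 3 && attr(pr, "n_below") >= 3) {
    expect_gt(cor(pr$Tb, pr$Cas, method = "spearman"), 0)
    expect_lt(cor(pr$Tb, pr$E, method = "spearman"), 0)
  }
})

test_that("the secondary response outgrows the paired primary response", {
  p <- ci_primary_run()
  s <- ci_secondary_run() # same seed as the primary helper
  gp <- glance(p); gs <- glance(s)
  expect_gte(gs$peak_size, gp$peak_size)
  expect_gt(gs$final_memory, gp$final_memory)
  # initial memory cells start from the resting memory profile: receptors high
  ms <- asymptotic_memory_state(s$config$molecular)
  first <- s$cells[s$cells$mcs == 0, ]
  expect_equal(unique(first$type), "memory")
  expect_equal(mean(first$R), ms$R, tolerance = 1e-6)
  expect_gt(ms$R, 10) # memory cells carry more IL2 receptors than naive (0)
})

test_that("tidiers and plots expose the run in standard forms", {
  s <- ci_primary_run()
  td <- tidy(s)
  expect_true(all(c("mcs", "day", "type", "count") %in% names(td)))
  expect_equal(nrow(td), nrow(s$population) * 6)
  g <- glance(s)
  expect_equal(nrow(g), 1)
  expect_true(g$contraction_death_fraction >= 0 && g$contraction_death_fraction <= 1)
  expect_s3_class(autoplot(s), "ggplot")
  expect_s3_class(plot_tbet_profile(tbet_profile(s)), "ggplot")
  expect_s3_class(plot_lattice(s), "ggplot")
  expect_output(print(s), "cd8_sim")
})

test_that("the unevenness sweep machinery varies m only and is deterministic at fixed seed", {
  cfg <- sim_config("ci", L = 40, n_mcs = 1500, n_naive = 4, n_apc = 1)
  set.seed(99)
  sw <- sweep_unevenness(cfg, m_values = c(0, 50), replicates = 2)
  expect_equal(nrow(sw), 4)
  expect_true(all(c("m", "replicate", "peak_size", "efficiency_ratio") %in% names(sw)))
  sm <- summarize_sweep(sw)
  expect_equal(sm$m, c(0, 50))
  # identical seed reproduces the sweep bit-for-bit
  set.seed(99)
  sw2 <- sweep_unevenness(cfg, m_values = c(0, 50), replicates = 2)
  expect_identical(sw, sw2)
  expect_s3_class(autoplot(sw), "ggplot")
})
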