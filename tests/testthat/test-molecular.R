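# The intracellular network: right-hand side, integration, bistability.

test_that("naive quiescence: the all-zero state is a fixed point without stimulation", {
  z <- molecular_state()
  d <- molecular_rhs(z, environment_inputs())
  expect_true(all(as.matrix(d) == 0))
  stepped <- step_molecular(z, environment_inputs(), dt = 0.5, n_steps = 20)
  expect_true(all(as.matrix(stepped) == 0))
})

test_that("rhs matches an independent term-by-term oracle on random inputs", {
  set.seed(101)
  p <- molecular_params()
  for (rep in 1:25) {
    x <- setNames(runif(6, 0, 150), c("R", "LR", "Tb", "Fs", "Cas", "E"))
    e <- c(f_APC = sample(0:3, 1), G = sample(0:1, 1), H = sample(0:1, 1),
           IL2cm = runif(1, 0, 2), Tbcm = runif(1, 0, 300))
    got <- molecular_rhs(molecular_state(x[1], x[2], x[3], x[4], x[5], x[6]),
                         environment_inputs(e[1], e[2], e[3], e[4], e[5]), p)
    expect_equal(unlist(got[1, ]), oracle_rhs(as.list(x), as.list(e), p),
                 tolerance = 1e-12)
  }
})

test_that("the Fas saturation-level switch changes only the Fs equation", {
  x <- molecular_state(R = 10, LR = 5, Tb = 40, Fs = 3, Cas = 4, E = 2)
  e <- environment_inputs(f_APC = 0, G = 1, H = 1, IL2cm = 0.5, Tbcm = 120)
  d1 <- molecular_rhs(x, e, molecular_params())
  d2 <- molecular_rhs(x, e, molecular_params(fas_cap_mode = "product"))
  expect_equal(d1[c("R", "LR", "Tb", "Cas", "E")], d2[c("R", "LR", "Tb", "Cas", "E")])
  p <- molecular_params()
  expect_equal(d2$Fs - d1$Fs,
               1 * p$mu_F_plus * 120 * (p$lam_F * p$k_F - p$lam_F / p$k_F),
               tolerance = 1e-12)
})

test_that("negative inputs are rejected", {
  expect_error(molecular_state(R = -1), "non-negative")
  expect_error(molecular_params(k_T = -0.1), "positive")
  expect_error(environment_inputs(G = 2), "0/1")
  expect_error(environment_inputs(f_APC = 1.5), "integer")
})

test_that("a single step reproduces the classical RK4 update", {
  p <- molecular_params()
  x0 <- c(R = 20, LR = 10, Tb = 30, Fs = 1, Cas = 5, E = 3)
  e <- c(f_APC = 1, G = 1, H = 0, IL2cm = 0.4, Tbcm = 0)
  h <- 1 / 600 # small enough that no subdivision triggers
  f <- function(x) oracle_rhs(as.list(x), as.list(e), p)
  k1 <- f(x0); k2 <- f(x0 + h / 2 * k1); k3 <- f(x0 + h / 2 * k2); k4 <- f(x0 + h * k3)
  expected <- x0 + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  got <- step_molecular(molecular_state(20, 10, 30, 1, 5, 3),
                        environment_inputs(1, 1, 0, 0.4, 0), p, dt = h)
  expect_equal(unlist(got[1, ]), setNames(expected, names(x0)), tolerance = 1e-12)
})

test_that("integration against a closed-form linear decay", {
  # with only R > 0 and no inputs, dR/dt = -k_R R has an exact solution
  p <- molecular_params()
  out <- step_molecular(molecular_state(R = 100), environment_inputs(), p,
                        dt = 1 / 60, n_steps = 600) # 10 h
  expect_equal(out$R, 100 * exp(-p$k_R * 10), tolerance = 1e-8)
})

test_that("non-negativity is preserved from random starts under random environments", {
  set.seed(202)
  p <- molecular_params()
  for (rep in 1:10) {
    x <- molecular_state(runif(1, 0, 50), runif(1, 0, 50), runif(1, 0, 150),
                         runif(1, 0, 20), runif(1, 0, 20), runif(1, 0, 30))
    e <- environment_inputs(sample(0:2, 1), 1, sample(0:1, 1), runif(1, 0, 1),
                            runif(1, 0, 250))
    out <- step_molecular(x, e, p, dt = 1 / 60, n_steps = 720)
    expect_true(all(as.matrix(out) >= 0))
    expect_true(all(is.finite(as.matrix(out))))
  }
})

test_that("Tbet fixed points match the grid sign-scan oracle on random parameter sets", {
  set.seed(303)
  for (rep in 1:100) {
    p <- molecular_params(
      lam_T2 = runif(1, 1, 30), lam_T3 = runif(1, 5, 120),
      n = sample(c(1, 2, 3, 4), 1), k_T = runif(1, 0.02, 0.4)
    )
    got <- tbet_fixed_points(p)
    exp_roots <- oracle_tbet_roots(p)
    expect_equal(got$root, exp_roots, tolerance = 1e-6)
    # bistability condition is exactly the three-root condition
    expect_equal(check_bistability(p), length(exp_roots) == 3)
  }
})

test_that("default Tbet fixed points sit at 0, 21 and 118 mol/L with correct stability", {
  fp <- tbet_fixed_points()
  expect_equal(fp$root, c(0, 21, 118), tolerance = 1e-8)
  expect_equal(fp$stable, c(TRUE, FALSE, TRUE))
  expect_true(check_bistability())
})

test_that("n = 1 never yields three fixed points", {
  expect_false(check_bistability(molecular_params(n = 1)))
  fp <- tbet_fixed_points(molecular_params(n = 1))
  expect_lte(nrow(fp), 2)
})

test_that("Tbet trajectories split at the unstable point (bistability)", {
  p <- molecular_params()
  env <- environment_inputs(G = 1)
  lo <- step_molecular(molecular_state(Tb = 21 * 0.9), env, p, dt = 0.25, n_steps = 1200)
  hi <- step_molecular(molecular_state(Tb = 21 * 1.1), env, p, dt = 0.25, n_steps = 1200)
  expect_lt(lo$Tb, 0.01 * 118)
  expect_equal(hi$Tb, 118, tolerance = 0.01)
})

test_that("the asymptotic memory state is a fixed point with the documented profile", {
  p <- molecular_params()
  ms <- asymptotic_memory_state(p)
  expect_equal(ms$Tb, 0, tolerance = 1e-6)
  expect_equal(ms$E, 26, tolerance = 0.01)
  expect_equal(ms$Cas, 9, tolerance = 0.01)
  res <- molecular_rhs(ms, environment_inputs(f_APC = 0, G = 1, H = 0), p)
  expect_lt(max(abs(as.matrix(res))), 1e-6)
})
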