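# Cell rules: cycle-length law, molecular partitioning, differentiation
# scheme, apoptosis.

test_that("cycle length law: bounds, direct values and limit", {
  expect_equal(cycle_length_mean(0), 6)
  expect_equal(cycle_length_mean(10), 6 + 2800 / 200) # = 20
  expect_equal(cycle_length_mean(1e9), 34, tolerance = 1e-6)
  set.seed(1)
  d0 <- sample_cycle_length(0, 1e5)
  expect_gte(min(d0), 2)  # minimum cycle length c_0 - 4 = 2 h
  expect_lte(max(d0), 10)
  expect_equal(mean(d0), 6, tolerance = 0.03)
  d10 <- sample_cycle_length(10, 1e4)
  expect_true(all(d10 >= 16 & d10 <= 24))
  expect_true(all(sample_cycle_length(0:50) > 0))
})

test_that("m = 0 partitioning gives two copies of the mother", {
  mother <- molecular_state(R = 3, LR = 1, Tb = 50, Fs = 2, Cas = 7, E = 11)
  set.seed(2)
  d <- partition_concentrations(mother, m = 0)
  expect_equal(as.matrix(d), rbind(as.matrix(mother)[1, ], as.matrix(mother)[1, ]),
               ignore_attr = TRUE)
})

test_that("partitioning conserves molecules exactly and respects the m-band", {
  set.seed(3)
  mother <- molecular_state(R = 10, LR = 4, Tb = 80, Fs = 1, Cas = 6, E = 14)
  mm <- as.matrix(mother)[1, ]
  n <- 20000
  fr <- matrix(NA_real_, n, 6)
  worst <- 0
  for (i in seq_len(n)) {
    d <- as.matrix(partition_concentrations(mother, m = 10))
    worst <- max(worst, abs(d[1, ] + d[2, ] - 2 * mm))
    fr[i, ] <- d[1, ] / (2 * mm)
  }
  expect_lt(worst, 1e-12) # molecule conservation at every single division
  # per-protein inherited fraction within [45%, 55%] at m = 10
  expect_gte(min(fr), 0.45 - 1e-12)
  expect_lte(max(fr), 0.55 + 1e-12)
  # coin-flip symmetry: mean fraction 50% (4 SE band, sd ~ 0.029)
  se <- 0.029 / sqrt(n)
  for (k in 1:6) expect_lt(abs(mean(fr[, k]) - 0.5), 4 * se)
})

test_that("asymmetric first division accumulates Tbet in the proximal daughter", {
  mother <- molecular_state(R = 5, LR = 2, Tb = 30, Fs = 0.5, Cas = 3, E = 1)
  set.seed(4)
  n <- 20000
  share <- numeric(n)
  worst_sum <- 0; worst_ratio <- c(Inf, -Inf)
  mm <- as.matrix(mother)[1, ]
  for (i in seq_len(n)) {
    d <- as.matrix(asymmetric_first_division(mother, m = 10))
    worst_sum <- max(worst_sum, abs(d[1, ] + d[2, ] - 2 * mm))
    ratio <- d[1, "Tb"] / d[2, "Tb"]
    worst_ratio <- c(min(worst_ratio[1], ratio), max(worst_ratio[2], ratio))
    share[i] <- d[1, "Tb"] / 60
  }
  expect_lt(worst_sum, 1e-12)            # conservation, Tbet included
  expect_gte(worst_ratio[1], 1 - 1e-12)  # proximal always >= distal
  expect_lte(worst_ratio[2], 3 + 1e-12)  # (2-K)/K for K in [0.5, 1]
  # E[(2 - K)/2] = 0.625 for K ~ U[0.5, 1]; sd of the share is 0.125/sqrt(12)
  expect_lt(abs(mean(share) - 0.625), 4 * (0.125 / sqrt(12)) / sqrt(n))
  # zero Tbet stays zero
  d0 <- asymmetric_first_division(molecular_state(), m = 10)
  expect_equal(d0$Tb, c(0, 0))
})

test_that("differentiation scheme follows the irreversible pathway", {
  th <- cd8_thresholds()
  expect_equal(apply_differentiation("naive", "apc_contact", molecular_state(), th),
               "pre_activated")
  expect_equal(apply_differentiation("memory", "apc_contact", molecular_state(), th),
               "pre_activated") # sanctioned re-entry on restimulation
  expect_equal(apply_differentiation("effector", "apc_contact", molecular_state(), th),
               "effector")
  # activation exactly at threshold ("reaches")
  expect_equal(apply_differentiation("pre_activated", "receptor_check",
                                     molecular_state(LR = th$IL2R_th), th),
               "activated")
  expect_equal(apply_differentiation("pre_activated", "receptor_check",
                                     molecular_state(LR = th$IL2R_th - 1e-9), th),
               "pre_activated")
  # daughter typing by Tbet at threshold
  expect_equal(apply_differentiation("activated", "division_daughter",
                                     molecular_state(Tb = th$Tbet_th), th),
               "effector")
  expect_equal(apply_differentiation("activated", "division_daughter",
                                     molecular_state(Tb = th$Tbet_th - 1e-9), th),
               "activated")
  # memory conversion at division is strict (>)
  expect_equal(apply_differentiation("effector", "division_check",
                                     molecular_state(E = th$Eomes_th), th),
               "effector")
  expect_equal(apply_differentiation("effector", "division_check",
                                     molecular_state(E = th$Eomes_th + 1e-9), th),
               "memory")
  expect_error(apply_differentiation("apc", "apc_contact", molecular_state(), th),
               "not a CD8")
})

test_that("apoptosis rules: Caspase threshold, naive immunity, APC lifetime", {
  th <- cd8_thresholds()
  expect_false(check_apoptosis("naive", Cas = 1e6, th))
  expect_true(check_apoptosis("effector", Cas = th$Caspases_th, th))
  expect_false(check_apoptosis("effector", Cas = th$Caspases_th - 1e-9, th))
  expect_true(check_apoptosis("apc", now = 50, apc_death_time = 49))
  expect_false(check_apoptosis("apc", now = 48, apc_death_time = 49))
  set.seed(5)
  lt <- sample_apc_lifetime(1e4)
  expect_true(all(lt >= 48 & lt <= 96))
  expect_gt(stats::ks.test(lt, "punif", 48, 96)$p.value, 0.01)
})

test_that("threshold constructor validates its inputs", {
  expect_error(cd8_thresholds(m = 150), "0, 100")
  expect_error(cd8_thresholds(Eomes_th = -1), "positive")
  th <- cd8_thresholds()
  expect_equal(th$Eomes_th, 16)
  expect_equal(th$Caspases_th, 19)
})
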