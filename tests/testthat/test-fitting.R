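test_that("rmsd objective matches its definition", {
  prots <- small_protocols()
  obs <- exact_quanta(fsin, prots)
  # model evaluated at the generating parameters: rmsd ~ 0
  expect_lt(rmsd_objective(fsin, obs, prots), 1e-10)
  # single AP identity: |model - data| for one point
  one <- list(single = build_train(1, 10, name = "single"))
  m1 <- simulate_protocol(one$single, fsin, cap0)$released_fraction
  d1 <- list(single = (m1 + 0.2) * fsin$n_sites)
  expect_equal(rmsd_objective(fsin, d1, one), 0.2)
})

test_that("problems validate their datasets", {
  prots <- small_protocols()
  expect_error(fit_problem(list(train_20hz_6 = 1:3), prots), "6 APs")
  expect_error(fit_problem(list(nope = 1:6), prots), "no protocol")
  obs <- exact_quanta(fsin, prots)
  expect_error(fit_problem(obs, prots, free = "n_sites"), "unknown free")
  expect_error(fit_problem(obs, prots, free = c("k2_scale", "s2")),
               "cannot be combined")
})

test_that("a fit with no free parameters returns the start unchanged", {
  prots <- small_protocols()
  obs <- exact_quanta(fsin, prots)
  ft <- fit_priming(obs, prots, start = fsin, free = character(0))
  expect_equal(unclass(ft$params), unclass(fsin))
  expect_lt(ft$rmsd, 1e-10)
})

test_that("one free parameter is recovered from noise-free data", {
  prots <- small_protocols()
  truth <- fsin; truth$p_fusion <- 0.45
  obs <- exact_quanta(truth, prots)
  ft <- fit_priming(obs, prots, start = fsin, free = "p_fusion",
                    n_starts = 3)
  expect_equal(ft$params$p_fusion, 0.45, tolerance = 0.01)
})

test_that("three free parameters are recovered from noise-free data", {
  prots <- standard_protocols()[c("train_5hz_15", "train_20hz_6",
                                  "train_100hz_15_rec110")]
  obs <- exact_quanta(fsin, prots)
  ft <- fit_priming(obs, prots, start = olm_start_fsin_scale(),
                    free = c("k2_0", "s2", "p_fusion"), n_starts = 6)
  truth <- c(fsin$k2_0, fsin$s2, fsin$p_fusion)
  expect_true(all(abs(coef(ft) - truth) / truth < 0.05))
})

test_that("reported rmsd equals the objective re-evaluated at the estimate", {
  prots <- small_protocols()
  obs <- exact_quanta(olm, prots)
  ft <- fit_priming(obs, prots, start = olm, free = "p_fusion",
                    n_starts = 2)
  expect_equal(ft$rmsd, rmsd_objective(ft$params, obs, prots))
})

test_that("fits are invariant to dataset ordering", {
  prots <- small_protocols()
  truth <- fsin; truth$k2_0 <- 0.6
  obs <- exact_quanta(truth, prots)
  f1 <- fit_priming(obs, prots, start = fsin, free = "k2_0", n_starts = 2)
  f2 <- fit_priming(rev(obs), prots, start = fsin, free = "k2_0",
                    n_starts = 2)
  expect_equal(f1$rmsd, f2$rmsd, tolerance = 1e-10)
  expect_equal(f1$params$k2_0, f2$params$k2_0, tolerance = 1e-8)
})

test_that("fits are reproducible under a fixed seed", {
  prots <- small_protocols()
  obs <- exact_quanta(olm, prots)
  f1 <- fit_priming(obs, prots, start = olm_start_fsin_scale(),
                    free = c("k2_0", "p_fusion"), n_starts = 3, seed = 7)
  f2 <- fit_priming(obs, prots, start = olm_start_fsin_scale(),
                    free = c("k2_0", "p_fusion"), n_starts = 3, seed = 7)
  expect_identical(coef(f1), coef(f2))
})

test_that("subset ladder identifies a planted single-parameter change", {
  prots <- small_protocols()
  truth <- fsin; truth$p_fusion <- 0.25
  obs <- exact_quanta(truth, prots)
  lad <- subset_ladder(obs, prots, base = fsin, sizes = 1,
                       n_starts = 2, seed = 3)
  top <- lad$table[lad$table$size == 1, ][1, ]
  expect_equal(top$subset, "p_fusion")
  expect_lt(top$rmsd, 1e-4)
})

test_that("best ladder rmsd is non-increasing in subset size", {
  prots <- small_protocols()
  truth <- fsin; truth$k2_0 <- 0.1; truth$p_fusion <- 0.4
  obs <- exact_quanta(truth, prots)
  lad <- subset_ladder(obs, prots, base = fsin, sizes = 1:2,
                       pool = c("k2_0", "s2", "b2", "p_fusion"),
                       n_starts = 2, seed = 5)
  best <- vapply(lad$best, `[[`, numeric(1), "rmsd")
  expect_true(all(diff(best) <= 1e-12))
})

test_that("the shared scaling factor of the second priming step is recovered", {
  prots <- standard_protocols()[c("train_20hz_6", "complex_rec110")]
  truth <- fsin
  truth$k2_0 <- 0.08 * fsin$k2_0
  truth$s2 <- 0.08 * fsin$s2
  truth$p_fusion <- 0.36
  obs <- exact_quanta(truth, prots)
  ft <- scaled_fit(obs, prots, base = fsin, n_starts = 5)
  expect_equal(ft$k2_scale, 0.08, tolerance = 0.05)
  expect_equal(ft$params$p_fusion, 0.36, tolerance = 0.02)
  # the constrained fit can never beat the corresponding free fit
  free3 <- fit_priming(obs, prots, start = fsin,
                       free = c("k2_0", "s2", "p_fusion"), n_starts = 4,
                       extra_starts = list(ft$params))
  expect_gte(ft$rmsd, free3$rmsd - 1e-12)
})

test_that("fit methods expose coefficients, predictions and residuals", {
  prots <- small_protocols()
  truth <- fsin; truth$p_fusion <- 0.5
  obs <- exact_quanta(truth, prots)
  ft <- fit_priming(obs, prots, start = fsin, free = "p_fusion",
                    n_starts = 2)
  expect_named(coef(ft), "p_fusion")
  expect_length(coef(ft, all = TRUE), 11)
  pred <- predict(ft)
  expect_named(pred, names(obs))
  expect_equal(pred$train_20hz_6, obs$train_20hz_6, tolerance = 1e-3)
  expect_lt(max(abs(residuals(ft))), 1e-4)
  expect_output(print(ft), "rmsd")
  expect_output(print(summary(ft)), "per-protocol")
})

test_that("noisy grand averages still recover the tight-state fraction", {
  # two seeded synthetic cohorts per connection type
  prots_f <- standard_protocols()[c("train_5hz_15", "train_20hz_6",
                                    "train_100hz_15_rec110")]
  for (sd in 1:2) {
    cfg <- generator_config(params = fsin, n_pairs = 25, seed = sd)
    q <- gta_quanta(generate_dataset(cfg, prots_f), initial_quanta = 5)
    ft <- fit_priming(q, prots_f, start = olm_start_fsin_scale(),
                      free = c("k2_0", "s2", "p_fusion"), n_starts = 4)
    expect_lt(abs(ft$derived$ts_fraction - 0.44), 0.05)
    expect_lt(abs(ft$params$p_fusion - 0.6) / 0.6, 0.10)
  }
  prots_o <- standard_protocols()[c("complex_rec110", "complex_rec1500")]
  start_o <- fsin; start_o$n_sites <- olm$n_sites
  for (sd in 1:2) {
    cfg <- generator_config(params = olm, n_pairs = 25, cv = 0.87, seed = sd)
    q <- gta_quanta(generate_dataset(cfg, prots_o), initial_quanta = 0.5)
    ft <- fit_priming(q, prots_o, start = start_o,
                      free = c("k2_0", "s2", "p_fusion"), n_starts = 4)
    expect_lt(abs(ft$derived$ts_fraction - 0.07), 0.05)
  }
})
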