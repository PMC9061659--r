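test_that("4-2 staircase recovers deterministic thresholds", {
  hfa <- instrument("hfa")
  # step-function responder at 25 dB, start at 25: forced trace ends at 25
  res <- threshold_staircase(25, 25, hfa, det_params(), seed = 1)
  expect_equal(res$threshold, 25)
  expect_false(res$saturated)
  # within 2 dB (one final step) from any start for noiseless observers
  for (S in c(8, 17, 31)) for (start in c(15, 25, 35)) {
    r <- threshold_staircase(S, start, hfa, det_params(), seed = S + start)
    expect_lte(abs(r$threshold - S), 2)
  }
  # far below the floor: recorded at the floor, saturated
  deep <- threshold_staircase(-15, 25, hfa, det_params(), seed = 2)
  expect_equal(deep$threshold, hfa$db_floor)
  expect_true(deep$saturated)
  # above the ceiling: recorded at the ceiling
  high <- threshold_staircase(55, 30, hfa, det_params(), seed = 3)
  expect_equal(high$threshold, hfa$db_ceiling)
})

test_that("staircase mean absolute error is small at sigma = 1", {
  hfa <- instrument("hfa")
  errs <- perisim:::with_seed(77, vapply(1:500, function(i) {
    r <- perisim:::run_stair(25, 25, hfa, sigma1_params(), c(4, 2), 30L)
    r$threshold - 25
  }, numeric(1)))
  expect_lte(mean(abs(errs)), 2)
})

test_that("full-grid staircase outcome is complete and deterministic", {
  obs <- noisy_normal_observer(1)
  o1 <- staircase_42(obs, seed = 42)
  o2 <- staircase_42(obs, seed = 42)
  expect_identical(o1$thresholds, o2$thresholds)
  expect_identical(o1$log, o2$log)
  expect_length(o1$thresholds, 76L)
  hfa <- instrument("hfa")
  expect_true(all(o1$thresholds >= hfa$db_floor &
                  o1$thresholds <= hfa$db_ceiling))
  expect_false(identical(o1$thresholds, staircase_42(obs, seed = 43)$thresholds))
})

test_that("the combine rule drops the most extreme estimate", {
  expect_equal(spark_combine(c(20, 20, 20, 20)), 20)
  expect_equal(spark_combine(c(10, 12, 13, 30)), mean(c(10, 12, 13)))
  expect_equal(spark_combine(c(0, 0, 0, 30)), 0)
  expect_error(spark_combine(c(1, 2, 3)), "4 finite")
  # oracle: brute force over all leave-one-out triples, min range
  oracle <- function(q) {
    trip <- utils::combn(4, 3)
    rng <- apply(trip, 2, function(ii) diff(range(q[ii])))
    mean(q[trip[, which.min(rng)]])
  }
  quads <- perisim:::with_seed(7, matrix(runif(4 * 2000, 0, 40), ncol = 4))
  got <- apply(quads, 1, spark_combine)
  want <- apply(quads, 1, oracle)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("phase plan: 6 seeds, 21 per refinement phase, full coverage", {
  sm <- assign_sectors(build_grid("SPARK66"))
  plan <- spark_plan(sm)
  expect_length(plan$seeds, 6L)
  for (ph in plan$phases) {
    expect_length(unique(ph), 21L)
    expect_length(intersect(ph, plan$seeds), 0L)   # seeds never re-tested
  }
  expect_length(intersect(plan$phases[[1]], plan$phases[[2]]), 0L)
  expect_setequal(c(plan$seeds, unlist(plan$phases)), 1:66)
})

test_that("phase 1 tests exactly six locations and reproduces constants", {
  obs <- uniform_observer(24, params = det_params())
  sm <- assign_sectors(build_grid("SPARK66"))
  tf <- instrument("twinfield2")
  p1 <- suppressWarnings(spark_phase1(obs, sm, tf, seed = 5))
  direct <- unique(p1$log$location[is.na(p1$log$catch)])
  expect_length(direct, 6L)
  expect_setequal(direct, sm$seeds$index)
  expect_length(p1$est, 66L)
  # uniform truth 24 dB ref = 14 dB on the k=30 instrument everywhere
  expect_equal(p1$est, rep(14, 66), tolerance = 1e-9)
  expect_warning(spark_phase1(obs, sm, tf, seed = 5), "regression model")
})

test_that("noiseless uniform observer is recovered by all four phases", {
  obs <- uniform_observer(24, params = det_params())
  tf <- instrument("twinfield2")
  out <- suppressWarnings(run_spark(obs, tf, seed = 9))
  expect_equal(dim(out$per_phase), c(66L, 4L))
  expect_equal(out$thresholds, rep(14, 66), tolerance = 1e-9)
  # every location directly tested at least once across phases 1-4
  direct <- unique(out$log$location[is.na(out$log$catch)])
  expect_setequal(direct, 1:66)
  expect_error(spark_refine_phase(obs, list(est = rep(14, 66),
                                            se = rep(1, 66)),
                                  phase = 5, assign_sectors(build_grid("SPARK66")),
                                  spark_plan(assign_sectors(build_grid("SPARK66"))),
                                  tf), "phase")
})

test_that("full spark run is deterministic with complete 66-point output", {
  obs <- noisy_normal_observer(2)
  model <- fit_seed_regression(training_bank(60))
  o1 <- run_spark(obs, regression_model = model, seed = 31)
  o2 <- run_spark(obs, regression_model = model, seed = 31)
  expect_identical(o1$thresholds, o2$thresholds)
  expect_identical(o1$log, o2$log)
  expect_length(o1$thresholds, 66L)
  tf <- instrument("twinfield2")
  expect_true(all(o1$thresholds >= tf$db_floor & o1$thresholds <= tf$db_ceiling))
  expect_true(is.na(o1$rates$fn))   # the strategy measures no FN catches
})

test_that("plateau: spark on k=30 can never report below 10 dB k=40-equivalent", {
  model <- fit_seed_regression(training_bank(60))
  tf <- instrument("twinfield2"); hfa <- instrument("hfa")
  obs <- simulate_cohort(cohort_config("glaucoma", 4, seed = 77,
                                       depth_range = c(20, 32)))
  for (o in obs) {
    sp <- run_spark(o, tf, model, seed = 50 + o$age)
    expect_true(all(convert_db(sp$thresholds, tf, hfa) >= 10))
  }
})

test_that("spark needs fewer presentations than the staircase", {
  model <- fit_seed_regression(training_bank(60))
  ratio <- vapply(1:6, function(i) {
    obs <- noisy_normal_observer(100 + i, params = sigma1_params())
    sp <- run_spark(obs, regression_model = model, seed = 200 + i)
    st <- staircase_42(obs, seed = 300 + i)
    c(sp$n_presentations, st$n_presentations)
  }, numeric(2))
  expect_lt(mean(ratio[1, ]), mean(ratio[2, ]))
  # direction of the halved test time: proxy ratio below 1
  expect_lt(mean(ratio[1, ]) / mean(ratio[2, ]), 0.75)
})

test_that("seed regression behaves like an interpolator of its training set", {
  # identical training fields: prediction reproduces that field
  g <- build_grid("SPARK66")
  const_field <- normal_field(g, age = 50, seed = 1, sector_sd = 0,
                              noise_sd = 0)$sensitivity
  train_const <- matrix(rep(const_field, each = 60), nrow = 60)
  m_const <- suppressWarnings(fit_seed_regression(train_const))
  expect_equal(predict_seed_model(m_const, const_field[m_const$seed_idx]),
               const_field, tolerance = 1e-3, ignore_attr = TRUE)
  # noisy training: seed locations approximately predict themselves
  train <- training_bank(200, seed = 9)
  m <- fit_seed_regression(train)
  for (j in seq_along(m$seed_idx)) {
    coefs <- m$coef[-1, m$seed_idx[j]]
    expect_gt(coefs[j], 0.9)
    expect_lt(max(abs(coefs[-j])), 0.1)
  }
  # held-out normals: beats the grand-mean predictor, RMSE < 1.5 * noise SD
  held <- training_bank(50, seed = 333)
  pred <- cbind(1, held[, m$seed_idx]) %*% m$coef
  rmse <- sqrt(mean((held - pred)^2))
  rmse_mean <- sqrt(mean((held - rowMeans(held))^2))
  expect_lt(rmse, rmse_mean)
  expect_lt(rmse, 1.5 * sqrt(1^2 + 0.5^2))
  expect_error(fit_seed_regression(train[1:10, ]), "at least 50")
})

test_that("catch trials estimate the configured rates", {
  g <- build_grid("SPARK66")
  obs <- uniform_observer(28, g, response_params(fp = 0.10, fn = 0.08,
                                                 fl = 0.20))
  rates <- catch_trials(list(fp = 1000, fn = 1000, fl = 1000), obs,
                        instrument("hfa"), seed = 13)
  expect_lt(abs(rates$fp - 0.10), 3 * sqrt(0.1 * 0.9 / 1000))
  expect_lt(abs(rates$fn - 0.08), 3 * sqrt(0.08 * 0.92 / 1000) + 0.01)
  fl_expect <- 0.20 + 0.80 * 0.10   # blind-spot hit: lost fixation or guess
  expect_lt(abs(rates$fl - fl_expect), 3 * sqrt(fl_expect * (1 - fl_expect) / 1000))
  # clean observer: near-zero FP
  clean <- uniform_observer(28, g, sigma1_params())
  expect_equal(catch_trials(list(fp = 400), clean, seed = 1)$fp, 0)
  # unscheduled types are absent, not zero
  sched <- catch_trials(list(fp = 10, fl = 10), obs, seed = 2)
  expect_true(is.na(sched$fn))
})
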