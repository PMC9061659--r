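test_that("normal fields follow the hill of vision and are seed-deterministic", {
  g <- build_grid("SPARK66")
  f1 <- normal_field(g, age = 50, seed = 11)
  f2 <- normal_field(g, age = 50, seed = 11)
  expect_identical(f1$sensitivity, f2$sensitivity)
  expect_false(identical(f1$sensitivity,
                         normal_field(g, age = 50, seed = 12)$sensitivity))
  # expected sensitivity decays with eccentricity: noiseless check
  f0 <- normal_field(g, age = 50, seed = 1, sector_sd = 0, noise_sd = 0)
  ecc <- sqrt(g$points$x^2 + g$points$y^2)
  expect_true(all(f0$sensitivity[ecc == min(ecc)] >
                  f0$sensitivity[ecc == max(ecc)]))
  # analytic mean: S0 - g*mean(ecc) - a*(age-20); averaged over fields
  expected <- 34 - 0.25 * mean(ecc) - 0.07 * 30
  means <- vapply(1:40, function(i)
    mean(normal_field(g, age = 50, seed = 100 + i)$sensitivity), numeric(1))
  expect_equal(mean(means), expected, tolerance = 0.15)
})

test_that("focal defects are local, non-increasing and midline-respecting", {
  g <- build_grid("SPARK66")
  f <- normal_field(g, age = 50, seed = 3, sector_sd = 0, noise_sd = 0)
  expect_identical(add_focal_defect(f, "superior_nasal", 0), f)
  def <- add_focal_defect(f, "superior_nasal", 30)
  sec <- perisim:::sector_rule(g$points$x, g$points$y)
  inside <- sec == "superior_nasal"
  expect_true(all(def$sensitivity <= f$sensitivity))
  expect_equal(def$sensitivity[inside], f$sensitivity[inside] - 30)
  # inferior temporal locations are untouched
  far <- sec == "inferior_temporal"
  expect_equal(def$sensitivity[far], f$sensitivity[far])
  # no bleed across the nasal horizontal midline
  inf_nasal <- sec == "inferior_nasal"
  expect_equal(def$sensitivity[inf_nasal], f$sensitivity[inf_nasal])
  # but adjacent superior temporal points may take partial loss
  expect_error(add_focal_defect(f, "arcuate", 10), "unknown sector")
})

test_that("diffuse loss shifts the mean exactly and spares pattern indices", {
  g <- build_grid("SPARK66")
  f <- normal_field(g, age = 55, seed = 9)
  d <- add_diffuse_loss(f, 5)
  expect_equal(mean(d$sensitivity), mean(f$sensitivity) - 5)
  expect_identical(add_diffuse_loss(f, 0)$sensitivity, f$sensitivity)
  td <- f$sensitivity - 30   # any reference surface
  expect_equal(psd(td - 5), psd(td))
  expect_equal(pattern_deviation(td - 5), pattern_deviation(td))
})

test_that("p_seen is a bounded monotone frequency-of-seeing curve", {
  prm <- response_params(fp = 0.05, fn = 0.04)
  s <- seq(-10, 50, by = 0.5)
  p <- p_seen(s, 25, prm)
  expect_true(all(diff(p) <= 0))
  expect_true(all(p >= prm$fp - 1e-12 & p <= 1 - prm$fn + 1e-12))
  # at threshold with no errors: exactly 0.5
  expect_equal(p_seen(25, 25, sigma1_params()), 0.5)
  # maximally bright limit approaches 1 - fn
  expect_equal(p_seen(-1e3, 25, response_params(fp = 0, fn = 0.05)), 0.95)
})

test_that("responses match p_seen frequencies (binomial oracle)", {
  g <- build_grid("SPARK66")
  obs <- uniform_observer(25, g, response_params(fp = 0.03, fn = 0.05,
                                                 sigma_min = 2, sigma_max = 2))
  for (stim in c(22, 25, 28)) {
    p <- p_seen(stim, 25, obs$params)
    hits <- perisim:::with_seed(stim * 101, {
      mean(vapply(1:10000, function(i) respond(stim, 1L, obs), logical(1)))
    })
    expect_lt(abs(hits - p), 3 * sqrt(p * (1 - p) / 10000))
  }
  # degenerate cases
  det <- uniform_observer(25, g, det_params())
  expect_true(all(vapply(1:50, function(i) respond(10, 2L, det), logical(1))))
  expect_false(any(vapply(1:50, function(i) respond(40, 2L, det), logical(1))))
  expect_error(respond(20, 67L, det), "off the observer")
})

test_that("cohorts are reproducible and match the requested structure", {
  cfg_g <- cohort_config("glaucoma", seed = 21)
  cfg_c <- cohort_config("cataract", seed = 22)
  expect_equal(cfg_g$n_subjects, 39L)
  expect_equal(cfg_c$n_subjects, 31L)
  g1 <- simulate_cohort(cohort_config("glaucoma", 8, seed = 5))
  g2 <- simulate_cohort(cohort_config("glaucoma", 8, seed = 5))
  expect_identical(lapply(g1, function(o) o$field$sensitivity),
                   lapply(g2, function(o) o$field$sensitivity))
  expect_length(g1, 8L)
  cc <- simulate_cohort(cohort_config("cataract", 6, seed = 5))
  expect_true(all(vapply(cc, function(o) o$group == "cataract", logical(1))))
  expect_error(cohort_config("glaucoma", defect_prob = c(1, 1, 0, 0)),
               "probability")
})

test_that("observers serialise to JSON losslessly", {
  obs <- simulate_cohort(cohort_config("glaucoma", 1, seed = 4))[[1]]
  path <- withr::local_tempfile(fileext = ".json")
  write_observer_json(obs, path)
  back <- read_observer_json(path)
  expect_equal(back$field$sensitivity, obs$field$sensitivity)
  expect_equal(back$age, obs$age)
  expect_equal(unclass(back$params), unclass(obs$params))
})
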