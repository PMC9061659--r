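# Uses a small staircase-based normative database shared across tests.
local_db <- local({
  db <- NULL
  function() {
    if (is.null(db)) db <<- build_normative_db(50, seed = 101)
    db
  }
})

test_that("mean sensitivity is a masked arithmetic mean", {
  expect_equal(mean_sensitivity(rep(30, 66)), 30)
  expect_equal(mean_sensitivity(c(20, 40)), 30)
  x <- runif(66, 10, 35)
  expect_equal(mean_sensitivity(x - 5), mean_sensitivity(x) - 5)
  mask <- seq_along(x) <= 10
  expect_equal(mean_sensitivity(x, mask), mean(x[-(1:10)]))
  expect_error(mean_sensitivity(numeric(0)), "no locations")
})

test_that("normative database is reproducible and age-aware", {
  db <- local_db()
  expect_equal(length(db$mean), 76L)
  db2 <- build_normative_db(50, seed = 101)
  expect_identical(db$mean, db2$mean)
  expect_identical(db$pd_cutoffs, db2$pd_cutoffs)
  # cut-offs are ordered: the 2% cut is at least as deep as the 5% cut
  expect_true(all(db$td_cutoffs["p2", ] <= db$td_cutoffs["p5", ] + 1e-12))
  # age slope is negative on average (sensitivity declines with age)
  expect_lt(mean(db$age_slope), 0)
  expect_warning(build_normative_db(50, seed = 1, levels = c(0.05, 0.005)),
                 "coarse")
  expect_error(build_normative_db(30, seed = 1), "at least 50")
  # JSON round-trip
  path <- withr::local_tempfile(fileext = ".json")
  write_normative_json(db, path)
  back <- read_normative_json(path)
  expect_equal(back$mean, db$mean)
  expect_equal(back$pd_cutoffs, db$pd_cutoffs, ignore_attr = TRUE)
})

test_that("total deviation is zero at the normative mean and local", {
  db <- local_db()
  base <- db$mean
  expect_equal(total_deviation(base, db, db$mean_age), rep(0, 76))
  expect_equal(total_deviation(base - 5, db, db$mean_age), rep(-5, 76))
  scot <- base; scot[40] <- scot[40] - 20
  td <- total_deviation(scot, db, db$mean_age)
  expect_equal(which(td != 0), 40L)
  expect_equal(td[40], -20)
  expect_error(total_deviation(base[1:66], db, 50), "mismatch")
})

test_that("pattern deviation absorbs general height", {
  td <- rep(-5, 66)
  expect_equal(pattern_deviation(td), rep(0, 66))
  td2 <- rep(0, 66); td2[10] <- -20
  pd2 <- pattern_deviation(td2)
  expect_equal(pd2[10], -20)
  expect_true(all(abs(pd2[-10]) < 1e-12))
  td3 <- runif(66, -10, 0)
  expect_equal(pattern_deviation(td3 + 7), pattern_deviation(td3))
})

test_that("MD and PSD have their closed forms and contrasts", {
  expect_equal(mean_deviation(rep(-5, 10)), -5)
  expect_equal(psd(rep(-5, 10)), 0)
  expect_equal(mean_deviation(c(0, -10)), -5)
  expect_equal(psd(c(0, -10)), 5)
  # diffuse loss moves MD, not PSD; focal loss moves both
  td <- rnorm(66, 0, 0.8)
  expect_equal(mean_deviation(td - 6), mean_deviation(td) - 6)
  expect_equal(psd(td - 6), psd(td))
  focal <- td; focal[1:8] <- focal[1:8] - 15
  expect_lt(mean_deviation(focal), mean_deviation(td))
  expect_gt(psd(focal), psd(td) + 2)
  expect_error(psd(numeric(0)), "empty")
})

test_that("NAPDP counts abnormal pattern-deviation points", {
  db <- local_db()
  expect_equal(napdp(rep(0, 76), db), 0L)
  deep <- rep(min(db$pd_cutoffs) - 1, 76)
  expect_equal(napdp(deep, db), 76L)
  mask <- abs(build_grid("30-2")$points$y) == 27
  expect_equal(sum(mask), 8L)              # top/bottom rows of 30-2
  expect_equal(napdp(deep, db, mask = mask), 68L)
  expect_error(napdp(rep(0, 76), db, level = 0.01), "not stored")
})

test_that("held-out normals are flagged at roughly the nominal rate", {
  db <- local_db()
  flags <- perisim:::with_seed(555, {
    vapply(1:50, function(i) {
      age <- runif(1, 40, 70)
      obs <- perisim:::new_observer("h", "normal", age,
                                    normal_field(build_grid("30-2"), age,
                                                 seed = 9000 + i),
                                    response_params())
      out <- staircase_42(obs, seed = 9500 + i)
      gi <- global_indices(out$thresholds, db, age)
      mean(gi$pd < db$pd_cutoffs["p5", ])
    }, numeric(1))
  })
  expect_lt(abs(mean(flags) - 0.05), 0.02)
})
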