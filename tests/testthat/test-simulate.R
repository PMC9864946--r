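test_that("the default design matches the standard trial protocol", {
  des <- simulation_design()
  expect_equal(des$temperatures_C, c(5, 10, 20, 25, 30))
  expect_identical(des$n_replicates, 4L)
  expect_identical(des$seeds_per_dish, 50L)
  expect_identical(des$stop_rule_days, 3L)
  expect_error(simulation_design(n_replicates = 0), "positive integer")
  expect_error(simulation_design(temperatures_C = numeric(0)), "non-empty")
})

test_that("simulation is deterministic under a fixed seed", {
  des <- simulation_design(rng_seed = 123)
  tm <- default_thermal()
  st <- dormancy_state(0.4, 3)
  a <- simulate_trialset(des, tm, st)
  b <- simulate_trialset(des, tm, st)
  expect_identical(a, b)
  # adding replicates never changes earlier ones
  des6 <- simulation_design(rng_seed = 123, n_replicates = 6L)
  c6 <- simulate_trialset(des6, tm, st)
  for (ti in seq_along(c6))
    expect_identical(c6[[ti]]$replicates[1:4], a[[ti]]$replicates)
  # a different seed gives a different census
  d2 <- simulate_trialset(simulation_design(rng_seed = 124), tm, st)
  expect_false(identical(a, d2))
})

test_that("every simulated census satisfies the seed-accounting invariants", {
  tm <- default_thermal()
  des <- simulation_design(rng_seed = 5)
  for (d in c(0, 0.3, 0.7, 1)) {
    for (ts in simulate_trialset(des, tm, dormancy_state(d, 3))) {
      expect_identical(length(ts$replicates), 4L)
      for (r in ts$replicates) {
        expect_s3_class(r, "time_course")  # constructor invariants hold
        expect_lte(sum(r$counts) + r$viable_ungerminated, r$seeds_sown)
      }
    }
  }
})

test_that("fully dormant seeds do not germinate anywhere (type 6)", {
  des <- simulation_design(rng_seed = 9, seeds_per_dish = 2000L,
                           temperatures_C = 20, n_replicates = 1L)
  tc <- simulate_trialset(des, default_thermal(), dormancy_state(1, 6),
                          leak = 0, dead_frac = 0)[[1]]$replicates[[1]]
  expect_identical(sum(tc$counts), 0L)
  expect_identical(tc$viable_ungerminated, 2000L)
})

test_that("the germinated fraction matches the window's gmax", {
  # d = 0.75 gives gmax = sqrt(0.25) = 0.5; 2000 seeds, binomial check
  des <- simulation_design(rng_seed = 21, seeds_per_dish = 2000L,
                           temperatures_C = 20, n_replicates = 1L)
  tc <- simulate_trialset(des, default_thermal(), dormancy_state(0.75, 6),
                          leak = 0, dead_frac = 0)[[1]]$replicates[[1]]
  # 4 binomial SDs of 0.5 at n = 2000 is 0.045
  expect_lt(abs(germination_fraction(tc) - 0.5), 0.05)
})

test_that("sub-base temperatures silently yield no germination", {
  des <- simulation_design(rng_seed = 2, temperatures_C = 3, n_replicates = 2L)
  tm <- thermal_model(Tb = 4)
  ts <- simulate_trialset(des, tm, dormancy_state(0, 6))[[1]]
  for (r in ts$replicates) expect_identical(sum(r$counts), 0L)
})

test_that("the census stop rule truncates after three germination-free days", {
  des <- simulation_design(rng_seed = 31, max_days = 60L)
  tm <- default_thermal()
  for (ts in simulate_trialset(des, tm, dormancy_state(0.5, 6))) {
    for (r in ts$replicates) {
      if (length(r$census_days) < 2) next
      gaps <- diff(r$census_days)
      # no recorded germination separated by more than the stop rule allows
      expect_true(all(gaps <= des$stop_rule_days))
    }
  }
})

test_that("dormancy release synchronises germination (two-level contrast)", {
  tm <- default_thermal()
  des <- simulation_design(rng_seed = 8)
  z_of <- function(d, base) vapply(1:60, function(i) {
    tc <- simulate_replicate(des, tm, dormancy_state(d, 6), 20,
                             seed = base + i)
    tryCatch(synchrony_index(tc), error = function(e) NA_real_)
  }, numeric(1))
  z_hi <- z_of(0.9, 30000)
  z_lo <- z_of(0.1, 60000)
  wt <- stats::wilcox.test(z_lo, z_hi, alternative = "greater", exact = FALSE)
  expect_lt(wt$p.value, 0.01)
  expect_gt(mean(z_lo, na.rm = TRUE), mean(z_hi, na.rm = TRUE))
})
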