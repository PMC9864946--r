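test_that("thermal time inverts to time to germination", {
  tm <- thermal_model(Tb = 5)
  expect_equal(time_to_germination(tm, 30, 20), 2)
  expect_equal(time_to_germination(tm, 30, 35), 1)
  expect_equal(time_to_germination(tm, 45, 10), 9)
  # round trip to machine precision
  tg <- time_to_germination(tm, 37.3, 18.2)
  expect_equal((18.2 - 5) * tg, 37.3, tolerance = 1e-15)
  expect_error(time_to_germination(tm, 30, 5), "sub-base")
  expect_error(time_to_germination(tm, 30, 4), "sub-base")
  expect_error(time_to_germination(tm, -1, 20), "positive")
  # strictly faster germination when warmer
  tgs <- time_to_germination(tm, 30, c(10, 15, 20, 25, 30))
  expect_true(all(diff(tgs) < 0))
})

test_that("model constructors validate their parameters", {
  expect_error(thermal_model(theta50 = -1), "positive")
  expect_error(thermal_model(theta_sigma = 0), "positive")
  expect_error(dormancy_state(1.2), "\\[0, 1\\]")
  expect_error(dormancy_state(0.5, pd_type = 7), "between 1 and 6")
  expect_error(dormancy_state(0.5, pd_type = 0), "between 1 and 6")
})

test_that("dormancy class tripartitions the dormancy level", {
  expect_identical(dormancy_class(c(1, 0.8, 0.7)), c("D", "D", "D"))
  expect_identical(dormancy_class(c(0.6, 0.5, 0.4)), c("CD", "CD", "CD"))
  expect_identical(dormancy_class(c(1 / 3, 0.2, 0)), c("ND", "ND", "ND"))
  expect_identical(dormancy_state(0.9, 3)$klass, "D")
})

test_that("niche windows follow the six non-deep PD types", {
  rng <- c(5, 30)
  # type 6: full taxon range even when fully dormant
  w6 <- niche_window(dormancy_state(1, 6), rng)
  expect_equal(c(w6$T_lo, w6$T_hi), rng)
  # type 3 fully dormant: intermediate only
  w3 <- niche_window(dormancy_state(1, 3), rng, T_mid = 20)
  expect_true(in_window(w3, 20))
  expect_false(in_window(w3, 5))
  expect_false(in_window(w3, 30))
  # type 1 fully dormant: low temperatures only
  w1 <- niche_window(dormancy_state(1, 1), rng)
  expect_true(all(in_window(w1, c(5, 10))))
  expect_false(any(in_window(w1, c(25, 30))))
  # type 2 fully dormant: high temperatures only
  w2 <- niche_window(dormancy_state(1, 2), rng)
  expect_true(in_window(w2, 30))
  expect_false(in_window(w2, 5))
  # nondormant types 1-3 reach the full range
  for (ty in 1:3) {
    w <- niche_window(dormancy_state(0, ty), rng, T_mid = 20)
    expect_equal(c(w$T_lo, w$T_hi), rng)
  }
})

test_that("window breadth is monotone in dormancy and contained in the range", {
  rng <- c(5, 30)
  ds <- seq(0, 1, by = 0.1)
  for (ty in 1:6) {
    breadth <- vapply(ds, function(d) {
      w <- niche_window(dormancy_state(d, ty), rng, T_mid = 20)
      expect_gte(w$T_lo, rng[1] - 1e-9)
      expect_lte(w$T_hi, rng[2] + 1e-9)
      expect_lte(w$T_lo, w$T_hi)
      w$T_hi - w$T_lo
    }, numeric(1))
    if (ty <= 3) {
      expect_true(all(diff(breadth) <= 1e-9))  # non-increasing in d
      expect_lt(breadth[length(breadth)], breadth[1])
    } else {
      expect_true(all(abs(breadth - breadth[1]) < 1e-9))  # constant in d
    }
    # germinable fraction rises as dormancy is released, 0 at full dormancy
    gm <- vapply(rev(ds), function(d)
      niche_window(dormancy_state(d, ty), rng, T_mid = 20)$gmax, numeric(1))
    expect_true(all(diff(gm) >= 0))
    expect_equal(gm[1], 0)
    expect_equal(gm[length(gm)], 1)
  }
  # logistic interpolation shares the endpoints
  wl <- niche_window(dormancy_state(0, 3), rng, T_mid = 20,
                     interpolation = "logistic")
  expect_equal(c(wl$T_lo, wl$T_hi), rng)
  # gmax floor applies to the fixed-window types only
  expect_equal(niche_window(dormancy_state(1, 6), rng, gmax_floor = 0.3)$gmax,
               0.3)
  expect_equal(niche_window(dormancy_state(1, 3), rng, gmax_floor = 0.3)$gmax,
               0)
})

test_that("dormancy release kinetics are exponential and agent-ordered", {
  expect_equal(dormancy_after_treatment(0.8, "after_ripening", 0), 0.8)
  # three half-lives at rate ln2/30
  expect_equal(
    dormancy_after_treatment(1, "after_ripening", 90, rate = log(2) / 30),
    0.125, tolerance = 1e-12)
  expect_lt(dormancy_after_treatment(1, "after_ripening", 1e6), 1e-8)
  # monotone non-increasing in duration, stays in [0, 1]
  d <- dormancy_after_treatment(0.9, "stratification", seq(0, 60, by = 5))
  expect_true(all(diff(d) < 0))
  expect_true(all(d >= 0 & d <= 1))
  # stratification works on a much shorter time scale than after-ripening:
  # 5 days of cold beat 5 days of dry storage by a wide margin
  expect_lt(dormancy_after_treatment(1, "stratification", 5),
            dormancy_after_treatment(1, "after_ripening", 5))
  expect_error(dormancy_after_treatment(1.5, "after_ripening", 1), "\\[0, 1\\]")
  expect_error(dormancy_after_treatment(0.5, "after_ripening", -1),
               "non-negative")
})
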