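test_that("time_course validates its census", {
  tc <- time_course(c(2, 3, 5), c(3, 0, 1), 50, 40)
  expect_s3_class(tc, "time_course")
  expect_identical(sum(tc$counts), 4L)

  expect_error(time_course(c(2, 2), c(1, 1), 50), "strictly increasing")
  expect_error(time_course(c(3, 2), c(1, 1), 50), "strictly increasing")
  expect_error(time_course(1:2, c(1, -1), 50), "non-negative")
  expect_error(time_course(1, 60, 50), "exceed seeds sown")
  expect_error(time_course(1, 10, 50, viable_ungerminated = 45),
               "exceed seeds sown")
  expect_error(time_course(0, 1, 50), "1-based")
  # empty census (nothing germinated) is a valid state
  expect_s3_class(time_course(integer(0), integer(0), 50, 47), "time_course")
})

test_that("relative frequencies divide by germinated seeds and sum to one", {
  expect_equal(relative_frequencies(time_course(1, 10, 50)), 1.0)
  expect_equal(relative_frequencies(c(5, 5)), c(0.5, 0.5))
  expect_equal(relative_frequencies(c(3, 0, 1)), c(0.75, 0, 0.25))
  expect_error(relative_frequencies(c(0, 0)), "undefined")
  set.seed(11)
  for (i in 1:50) expect_equal(sum(relative_frequencies(random_counts())), 1)
})

test_that("asynchrony index is the base-2 entropy of germination timing", {
  expect_equal(asynchrony_index(time_course(4, 10, 50)), 0)
  expect_equal(asynchrony_index(c(5, 5)), 1)
  # hand evaluation of -0.75 log2 0.75 - 0.25 log2 0.25
  expect_equal(asynchrony_index(c(3, 1)), 0.811278124459133, tolerance = 1e-12)
  # zero-count days carry no mass
  expect_equal(asynchrony_index(c(3, 0, 1)), asynchrony_index(c(3, 1)))
  expect_error(asynchrony_index(time_course(integer(0), integer(0), 50)),
               "undefined")
})

test_that("pair combinations count unordered pairs exactly", {
  expect_identical(pair_combinations(0), 0)
  expect_identical(pair_combinations(1), 0)
  expect_identical(pair_combinations(2), 1)
  expect_identical(pair_combinations(50), 1225)
  expect_equal(pair_combinations(c(3, 4)), c(3, 6))
  expect_error(pair_combinations(-1), "non-negative")
})

test_that("synchrony index hits its boundary values", {
  # all seeds on one day
  expect_identical(synchrony_index(time_course(3, 10, 50)), 1)
  # one seed per day: no pair shares a day
  expect_identical(synchrony_index(time_course(1:4, rep(1, 4), 50)), 0)
  # 45 pairs among 10 seeds, 2 * C(5,2) = 20 on a shared day
  expect_equal(synchrony_index(c(5, 5)), 20 / 45)
  expect_error(synchrony_index(time_course(1, 1, 50)), "undefined")
  expect_error(synchrony_index(time_course(integer(0), integer(0), 50)),
               "undefined")
})

test_that("synchrony equals explicit pair enumeration on random censuses", {
  set.seed(42)
  for (i in 1:200) {
    x <- random_counts()
    expect_identical(synchrony_index(x), enumerate_pair_fraction(x))
  }
})

test_that("index properties hold over random censuses", {
  set.seed(99)
  for (i in 1:200) {
    x <- random_counts()
    z <- synchrony_index(x)
    e <- asynchrony_index(x)
    k <- sum(x > 0)
    expect_gte(z, 0); expect_lte(z, 1)
    expect_gte(e, 0)
    # entropy bounded by log2(days with germination)
    expect_lte(e, log2(k) + 1e-12)
    # Z = 1 and E = 0 exactly when a single day holds all germination
    expect_identical(z == 1, k == 1L)
    expect_identical(e == 0, k == 1L)
    # day labels are irrelevant: permuting counts changes nothing
    p <- sample(length(x))
    expect_equal(synchrony_index(x[p]), z)
    expect_equal(asynchrony_index(x[p]), e)
    # merging two days never decreases Z, never increases E
    if (length(x) >= 2) {
      ij <- sample(length(x), 2)
      merged <- x[-ij[2]]
      merged[which(seq_along(x)[-ij[2]] == ij[1])] <- x[ij[1]] + x[ij[2]]
      expect_gte(synchrony_index(merged), z - 1e-12)
      expect_lte(asynchrony_index(merged), e + 1e-12)
    }
  }
})

test_that("uniform k-day germination attains the entropy bound", {
  for (k in 2:8) {
    expect_equal(asynchrony_index(rep(7, k)), log2(k), tolerance = 1e-12)
    # any non-uniform spread over k days stays strictly below
    x <- rep(7, k); x[1] <- x[1] + 3
    expect_lt(asynchrony_index(x), log2(k))
  }
})

test_that("germination fraction supports sown and viable denominators", {
  tc <- time_course(c(1, 2), c(10, 10), 50, viable_ungerminated = 5)
  expect_equal(germination_fraction(tc, "sown"), 0.4)
  expect_equal(germination_fraction(tc, "viable"), 20 / 25)
  expect_equal(germination_fraction(time_course(1, 0, 50, 0), "sown"), 0)
  expect_equal(
    germination_fraction(time_course(1, 20, 50, viable_ungerminated = 5),
                         "viable"), 0.8)
  expect_error(
    germination_fraction(time_course(1, 0, 50, 0), "viable"), "undefined")
})
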