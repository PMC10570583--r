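test_that("cost factors are cost ratios rounded half-up with floor 1", {
  expect_identical(cost_factor(4711, 4711), 1L)
  expect_identical(cost_factor(1565000, 4711), 332L)
  expect_identical(cost_factor(20235, 4711), 4L)
  # 4.295 rounds down, 4.5 rounds up (half-up, not banker's)
  expect_identical(cost_factor(4.5, 1), 5L)
  expect_identical(cost_factor(3.5, 1), 4L)
  # classes cheaper than the reference floor at 1
  expect_identical(cost_factor(100, 1000), 1L)
  expect_error(cost_factor(-1, 10), "positive")
  expect_error(cost_factor(10, 0), "positive")
})

test_that("aggregate cost rescaling and per-event cost are exact ratios", {
  expect_equal(scale_total_cost(55e9, 38000, 38000), 55e9)
  expect_equal(scale_total_cost(100, 4, 2), 50)
  # 2018 crash-death cost rescaled to the 2019 death count: ~ $52 billion
  expect_equal(scale_total_cost(55e9, 38000, 36000) / 1e9, 52.105,
               tolerance = 1e-4)
  expect_error(scale_total_cost(1, 0, 10), "positive")

  expect_equal(per_event_cost(10, 10), 1)
  expect_equal(per_event_cost(1e6, 4), 250000)
  # $52e9 over 33,244 fatal crashes: the schema's rounded $1,565,000
  expect_equal(per_event_cost(52e9, 33244), 1564192.03, tolerance = 1e-8)
  expect_error(per_event_cost(1, 0), "positive")
})

test_that("normalized severity factors are cost-weighted count shares", {
  sch <- severity_schema(
    class = c("Fatal", "Major", "Minor"),
    avg_cost = c(1565000, 20235, 4711),
    count = c(33244, 1916000, 4806000),
    reference = "Minor")
  sch <- normalize_severity(sch)
  expect_equal(unname(sch$cost_factors), c(332L, 4L, 1L))
  expect_equal(unname(sch$weighted_counts), c(11037008, 7664000, 4806000))
  expect_equal(unname(round(sch$normalized_factors, 3)),
               c(0.470, 0.326, 0.204))
  expect_equal(sum(sch$normalized_factors), 1, tolerance = 1e-12)

  one <- normalize_severity(severity_schema("A", avg_cost = 5, count = 7))
  expect_equal(unname(one$normalized_factors), 1)

  flat <- normalize_severity(severity_schema(
    c("a", "b", "c"), avg_cost = c(1, 1, 1), count = c(1, 1, 2)))
  expect_equal(unname(flat$normalized_factors), c(0.25, 0.25, 0.50))

  zero <- severity_schema(c("a", "b"), avg_cost = c(2, 1), count = c(0, 0))
  expect_error(normalize_severity(zero), "degenerate")
})

test_that("normalized factors are cost-scale invariant, unit-sum, and count-monotone", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(2:6, 1)
    costs <- sort(exp(stats::runif(n, 0, 8)), decreasing = TRUE)
    counts <- stats::rpois(n, 5000) + 1
    sch <- normalize_severity(severity_schema(
      paste0("c", 1:n), avg_cost = costs, count = counts))
    expect_equal(sum(sch$normalized_factors), 1, tolerance = 1e-9)

    scaled <- normalize_severity(severity_schema(
      paste0("c", 1:n), avg_cost = costs * 3.7, count = counts))
    expect_equal(scaled$normalized_factors, sch$normalized_factors,
                 tolerance = 1e-12)

    bumped <- normalize_severity(severity_schema(
      paste0("c", 1:n), avg_cost = costs,
      count = counts + c(1000, rep(0, n - 1))))
    expect_gt(bumped$normalized_factors[1], sch$normalized_factors[1])
    expect_true(all(bumped$normalized_factors[-1] <
                      sch$normalized_factors[-1]))
  }
})

test_that("severity CSV reader strips comma and prime thousands separators", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("class,consequence,avg_cost,count",
               "Fatal,Fatal,1′565′000,33'244",
               "Minor,Property,\"4,711\",\"4,806,000\""), path)
  sch <- read_severity_csv(path, reference = "Minor")
  expect_equal(unname(sch$classes$avg_cost), c(1565000, 4711))
  expect_equal(unname(sch$classes$count), c(33244, 4806000))
  expect_equal(unname(sch$cost_factors), c(332L, 1L))
})

test_that("severity JSON serialization preserves factors at full precision", {
  sch <- normalize_severity(severity_schema(
    c("A", "B"), avg_cost = c(300, 100), count = c(1, 2)))
  parsed <- jsonlite::fromJSON(write_severity_json(sch))
  expect_equal(parsed$cost_factors$A, 3)
  expect_equal(parsed$normalized_factors$A, 3 / 5, tolerance = 1e-15)
})
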