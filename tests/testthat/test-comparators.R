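test_that("comparator inputs derive best/worst and priorities from scores", {
  q <- saaty_quantizer()
  inp <- derive_comparator_inputs(printed_scores$driver_state, q)
  expect_equal(inp$bwm$labels[inp$bwm$best], "R5")
  expect_equal(inp$bwm$labels[inp$bwm$worst], "R6")
  expect_equal(inp$bwm$best_to_others, c(1, 9))  # 18.2/2.0 = 9.1 -> 9

  beh <- derive_comparator_inputs(printed_scores$driver_behavior, q)
  expect_equal(beh$fucom$labels, c("R7", "R9", "R8"))
  expect_equal(beh$fucom$priorities, c(2, 2))

  expect_warning(
    eqin <- derive_comparator_inputs(c(a = 3, b = 3), q), "ties")
  expect_equal(eqin$bwm$best_to_others, c(1, 1))
  expect_equal(eqin$fucom$priorities, 1)

  expect_error(bwm_input(c("a", "b"), 1, 2, c(2, 9), c(9, 1)), "must be 1")
  expect_error(fucom_input(c("a", "b", "c"), c(0.5, 2)), ">= 1")
})

test_that("BWM solver recovers consistent weights and the 2-factor closed form", {
  # perfectly consistent vectors from w = (0.6, 0.3, 0.1)
  w <- c(0.6, 0.3, 0.1)
  inp <- bwm_input(c("a", "b", "c"), 1, 3, w[1] / w, w / w[3])
  sol <- bwm_weights(inp)
  expect_lt(sol$xi, 1e-8)
  expect_true(sol$consistent)
  expect_equal(unname(sol$weights), w, tolerance = 1e-6)

  two <- bwm_weights(bwm_input(c("a", "b"), 1, 2, c(1, 9), c(9, 1)))
  expect_equal(unname(two$weights), c(0.9, 0.1), tolerance = 1e-6)
})

test_that("BWM solver agrees with the simplex grid-search oracle", {
  # sharp optimum: weights are pinned down to the grid resolution
  sol <- bwm_weights(bwm_input(c("a", "b", "c"), 1, 3,
                               c(1, 2, 4), c(4, 2, 1)))
  oracle <- grid_minimax_oracle(bwm_dev_rows(1, 3, c(1, 2, 4), c(4, 2, 1)),
                                3, coarse = 0.005)
  expect_lt(max(abs(unname(sol$weights) - oracle$weights)), 2e-3)
  expect_lte(sol$xi, oracle$value + 1e-6)

  # nearly flat optimum: the attained min-max deviation must agree even
  # though the argmin is not unique at this resolution
  dev4 <- bwm_dev_rows(2, 4, c(3, 1, 2, 7), c(3, 7, 4, 1))
  sol4 <- bwm_weights(bwm_input(paste0("f", 1:4), 2, 4,
                                c(3, 1, 2, 7), c(3, 7, 4, 1)))
  oracle4 <- grid_minimax_oracle(dev4, 4, coarse = 0.02)
  expect_lte(sol4$xi, oracle4$value + 1e-6)
  expect_lt(abs(sol4$xi - oracle4$value), 1e-3)
  expect_equal(dev4(matrix(unname(sol4$weights), 1)), sol4$xi,
               tolerance = 1e-9)
})

test_that("FUCOM solver solves consistent chains exactly and matches the oracle", {
  chain <- fucom_weights(fucom_input(c("a", "b", "c"), c(2, 2)))
  expect_equal(unname(chain$weights), c(4, 2, 1) / 7, tolerance = 1e-8)
  expect_lt(chain$chi, 1e-8)

  unif <- fucom_weights(fucom_input(paste0("x", 1:4), c(1, 1, 1)))
  expect_equal(unname(unif$weights), rep(0.25, 4), tolerance = 1e-6)

  for (cs in list(list(phi = c(1.5, 2.5)),
                  list(phi = c(2, 1.2, 3)))) {
    n <- length(cs$phi) + 1
    sol <- fucom_weights(fucom_input(paste0("f", 1:n), cs$phi))
    oracle <- grid_minimax_oracle(fucom_dev_rows(cs$phi), n,
                                  coarse = if (n == 3) 0.005 else 0.02)
    expect_lt(max(abs(unname(sol$weights) - oracle$weights)), 2e-3)
  }
})

test_that("solver outputs are positive unit-sum with nonnegative deviations", {
  set.seed(99)
  for (k in 1:5) {
    n <- sample(3:5, 1)
    a_b <- c(1, sample(2:9, n - 1, replace = TRUE))
    a_b[n] <- max(a_b)
    a_w <- c(a_b[n], sample(1:5, n - 2, replace = TRUE), 1)
    sol <- bwm_weights(bwm_input(paste0("f", 1:n), 1, n, a_b, a_w))
    expect_true(all(sol$weights > 0))
    expect_equal(sum(sol$weights), 1, tolerance = 1e-9)
    expect_gte(sol$xi, 0)

    phi <- runif(n - 1, 1, 3)
    fsol <- fucom_weights(fucom_input(paste0("f", 1:n), phi))
    expect_true(all(fsol$weights > 0))
    expect_equal(sum(fsol$weights), 1, tolerance = 1e-9)
    expect_gte(fsol$chi, 0)
  }
})

test_that("AHP, BWM, and FUCOM coincide on noise-free ratio inputs", {
  w <- c(A = 0.5, B = 0.3, C = 0.2)
  scores <- w * 100
  ahp <- ahp_weights(build_from_scores(scores, q = NULL))
  inp <- derive_comparator_inputs(scores, q = NULL)
  bwm <- bwm_weights(inp$bwm)$weights
  fucom <- fucom_weights(inp$fucom)$weights[names(w)]
  expect_equal(unname(ahp), unname(w), tolerance = 1e-6)
  expect_equal(unname(bwm), unname(w), tolerance = 1e-6)
  expect_equal(unname(fucom), unname(w), tolerance = 1e-6)
})

test_that("the three methods agree on the case-study extremes and on top factors under noise", {
  cmp <- compare_methods(us_config())
  expect_equal(unname(cmp$ranks[, "R5"]), rep(1, 3))
  expect_equal(unname(cmp$ranks[, "R1"]), rep(9, 3))
  expect_gte(cmp$max_divergence, 0)

  # mild multiplicative noise on the score ratios must not flip the top factor
  base <- c(F1 = 45, F2 = 25, F3 = 18, F4 = 12)
  set.seed(2023)
  for (k in 1:5) {
    noisy <- base * exp(rnorm(4, sd = 0.1))
    ahp_top <- names(which.max(ahp_weights(build_from_scores(noisy, NULL))))
    inp <- derive_comparator_inputs(noisy, q = NULL)
    bwm_top <- names(which.max(bwm_weights(inp$bwm)$weights))
    fucom_top <- names(which.max(fucom_weights(inp$fucom)$weights))
    expect_equal(ahp_top, "F1")
    expect_equal(bwm_top, "F1")
    expect_equal(fucom_top, "F1")
  }
})
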