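test_that("column normalization makes columns stochastic, matching the printed tables", {
  cn <- column_normalize(pcm(printed_criteria_pcm))
  expect_equal(unname(cn[, 1]), c(0.100, 0.400, 0.500))
  expect_equal(colSums(cn), c(C1 = 1, C2 = 1, C3 = 1))

  cn_env <- column_normalize(pcm(printed_env_pcm))
  expect_equal(unname(round(cn_env[, 1], 3)), c(0.083, 0.250, 0.417, 0.250))
  expect_equal(unname(colSums(cn_env)), rep(1, 4))

  ones <- column_normalize(matrix(1, 3, 3))
  expect_true(all(abs(ones - 1 / 3) < 1e-15))
})

test_that("power iteration recovers the principal eigenvector", {
  # closed form for the 2x2 matrix
  w2 <- ahp_weights(pcm(printed_state_pcm))
  expect_equal(unname(w2), c(0.9, 0.1), tolerance = 1e-12)

  w3 <- ahp_weights(pcm(printed_behavior_pcm))
  expect_equal(unname(round(w3, 3)), c(0.493, 0.196, 0.311))

  # consistent ratio matrix: exact recovery (Aw = nw)
  v <- c(0.55, 0.25, 0.12, 0.08)
  cons <- pcm(outer(v, v, "/"), paste0("F", 1:4))
  expect_equal(unname(ahp_weights(cons)), v, tolerance = 1e-12)
  expect_equal(lambda_max(cons, ahp_weights(cons)), 4, tolerance = 1e-10)
})

test_that("eigen and row-mean weights agree closely on consistent-enough matrices", {
  for (m in list(printed_criteria_pcm, printed_env_pcm,
                 printed_behavior_pcm)) {
    p <- pcm(m)
    expect_lt(max(abs(ahp_weights(p, "eigen") - ahp_weights(p, "rowmean"))),
              0.005)
  }
})

test_that("power iteration matches a dense eigen-decomposition oracle", {
  for (seed in 1:20) {
    n <- 2 + (seed %% 3)  # orders 2..4
    gp <- generate_pcm(synthetic_spec(n, noise_sigma = 0.2, seed = seed))
    mine <- ahp_weights(gp$pcm)
    e <- eigen(unclass(as.matrix(gp$pcm)))
    i <- which.max(Re(e$values))
    ref <- Re(e$vectors[, i])
    ref <- ref / sum(ref)
    expect_lt(max(abs(mine - ref)), 1e-9)
  }
})

test_that("lambda-max estimator is n for consistent matrices and >= n otherwise", {
  v <- c(0.6, 0.3, 0.1)
  cons <- pcm(outer(v, v, "/"), c("a", "b", "c"))
  expect_equal(lambda_max(cons, ahp_weights(cons)), 3, tolerance = 1e-10)
  expect_error(lambda_max(cons, c(0.5, 0.5, 0)), "positive")
  expect_error(lambda_max(cons, c(0.5, 0.5)), "length")

  for (seed in 31:45) {
    n <- 2 + (seed %% 5)
    gp <- generate_pcm(synthetic_spec(n, noise_sigma = 0.5, seed = seed))
    lm <- lambda_max(gp$pcm, ahp_weights(gp$pcm))
    expect_gte(lm, n - 1e-12)
  }
})

test_that("consistency reports implement CI, RI lookup, and the 0.10 rule", {
  rep <- consistency(3.0055, 3)
  expect_equal(rep$ci, 0.00275)
  expect_equal(round(rep$cr, 6), 0.004741)
  expect_true(rep$passed)

  expect_equal(round(consistency(3.0537, 3)$cr, 6), 0.046293)
  expect_equal(round(consistency(4.0042, 4)$cr, 6), 0.001556)

  perfect <- consistency(4.0, 4)
  expect_equal(perfect$ci, 0)
  expect_equal(perfect$cr, 0)

  # no inconsistency is possible at n = 2
  expect_equal(consistency(2.0, 2)$cr, 0)
  expect_true(consistency(2.0, 2)$passed)

  expect_false(consistency(3.8, 3)$passed)
  expect_error(consistency(9.5, 9), "extended")
  expect_equal(consistency(9.5, 9, extended = TRUE)$ri, 1.45)
  expect_equal(saaty_random_index(8), 1.41)
  expect_true(all(diff(vapply(1:8, saaty_random_index, numeric(1))) >= 0))
})

test_that("matrix-level consistency follows the classical rounded-estimator convention", {
  # row-mean weights, estimator rounded to 4 decimals before CI/CR
  expect_equal(pcm_consistency(pcm(printed_criteria_pcm))$lambda_max, 3.0055)
  expect_equal(pcm_consistency(pcm(printed_env_pcm))$lambda_max, 4.0042)
  expect_equal(pcm_consistency(pcm(printed_behavior_pcm))$lambda_max, 3.0537)
  # exact-eigenvalue convention is available and unrounded
  ex <- pcm_consistency(pcm(printed_behavior_pcm), "eigen")
  expect_equal(ex$lambda_max, 3.053622, tolerance = 1e-6)
  expect_equal(ex$convention, "eigen")
})

test_that("synthesis multiplies local by parent weights and conserves mass", {
  crit <- c(C1 = 0.101, C2 = 0.433, C3 = 0.466)
  local <- list(
    C1 = c(R1 = 0.082, R2 = 0.235, R3 = 0.448, R4 = 0.235),
    C2 = c(R5 = 0.900, R6 = 0.100),
    C3 = c(R7 = 0.493, R8 = 0.196, R9 = 0.311))
  g <- synthesize(crit, local)
  expect_equal(round(g[["R5"]], 3), 0.390)
  expect_equal(round(g[["R7"]], 3), 0.230)
  expect_equal(sum(g), 1, tolerance = 1e-9)

  expect_equal(unname(synthesize(c(A = 1), list(A = c(x = 1)))), 1)
  expect_error(synthesize(crit, local[c("C1", "C2")]), "incomplete")
  expect_error(synthesize(c(C1 = 0.7, C2 = 0.7),
                          list(C1 = c(a = 1), C2 = c(b = 1))), "sum to 1")
})

test_that("competition ranking shares the smallest rank on ties and skips after", {
  g <- c(R1 = 0.008, R2 = 0.024, R3 = 0.045, R4 = 0.024, R5 = 0.390,
         R6 = 0.043, R7 = 0.230, R8 = 0.091, R9 = 0.145)
  rk <- rank_factors(g)
  expect_equal(rk$label, c("R5", "R7", "R9", "R8", "R3", "R6", "R2", "R4",
                           "R1"))
  expect_equal(rk$rank, c(1, 2, 3, 4, 5, 6, 7, 7, 9))
  expect_equal(rk$tied, c(rep(FALSE, 6), TRUE, TRUE, FALSE))

  all_eq <- rank_factors(c(a = 1 / 3, b = 1 / 3, c = 1 / 3))
  expect_equal(all_eq$rank, c(1, 1, 1))
  expect_true(all(all_eq$tied))

  plain <- rank_factors(c(x = 0.5, y = 0.3, z = 0.2))
  expect_equal(plain$rank, 1:3)
  expect_false(any(plain$tied))

  # permutation invariance of leaf labels
  perm <- sample(names(g))
  rk2 <- rank_factors(g[perm])
  expect_equal(rk2$rank[match(rk$label, rk2$label)], rk$rank)
})
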