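test_that("self-evaluation and hand-solved two-DMU programs", {
  # single DMU is its own frontier
  p1 <- dea_problem(matrix(3), matrix(5), "input")
  r1 <- solve_vrs(p1, 1)
  expect_equal(r1$rte, 1)
  expect_equal(r1$efficiency_class, "efficient")
  expect_equal(r1$lambdas, 1)
  # A uses 1 input for 1 output, B uses 2 for the same output:
  # B can contract to theta = 0.5 against peer A
  p2 <- dea_problem(matrix(c(1, 2)), matrix(c(1, 1)), "input")
  r2 <- solve_all(p2)
  expect_equal(r2[[1]]$rte, 1)
  expect_equal(r2[[2]]$rte, 0.5)
  expect_equal(r2[[2]]$lambdas, c(1, 0), tolerance = 1e-9)
  expect_equal(r2[[2]]$efficiency_class, "inefficient")
  # output orientation: same input, B makes twice the output, so A can
  # expand by phi = 2 and reports rte = 1/phi = 0.5
  p3 <- dea_problem(matrix(c(1, 1)), matrix(c(1, 2)), "output")
  r3 <- solve_all(p3)
  expect_equal(r3[[1]]$raw_objective, 2)
  expect_equal(r3[[1]]$rte, 0.5)
  expect_equal(r3[[2]]$rte, 1)
})

test_that("identical DMUs are both on the frontier", {
  X <- matrix(c(2, 2), 2, 1); Y <- matrix(c(3, 3), 2, 1)
  res <- solve_all(dea_problem(X, Y, "input"))
  expect_equal(vapply(res, `[[`, numeric(1), "rte"), c(1, 1))
})

test_that("scores are bounded, someone is efficient, and inputs floored", {
  set.seed(501)
  X <- matrix(runif(19 * 4, 0.5, 5), 19, 4)
  Y <- matrix(runif(19 * 2, 0.5, 5), 19, 2)
  res <- solve_all(dea_problem(X, Y, "input"))
  rte <- vapply(res, `[[`, numeric(1), "rte")
  expect_true(all(rte >= 0 & rte <= 1 + 1e-9))
  expect_gte(sum(abs(rte - 1) < 1e-6), 1)
  expect_true(all(vapply(res, `[[`, numeric(1), "slack_total") >= -1e-9))
  lam <- vapply(res, function(r) sum(r$lambdas), numeric(1))
  expect_equal(lam, rep(1, 19), tolerance = 1e-7)
  # zero inputs do not break the program
  X0 <- X; X0[1, 1] <- 0
  expect_silent(solve_all(dea_problem(X0, Y, "input")))
})

test_that("worsening an input never improves the input-oriented score", {
  set.seed(502)
  X <- matrix(runif(8 * 2, 1, 4), 8, 2)
  Y <- matrix(runif(8, 1, 4), 8, 1)
  base <- solve_vrs(dea_problem(X, Y, "input"), 3)$rte
  for (mult in c(1.1, 1.5, 3)) {
    X2 <- X; X2[3, 1] <- mult * X2[3, 1]
    expect_lte(solve_vrs(dea_problem(X2, Y, "input"), 3)$rte,
               base + 1e-9)
  }
})

test_that("scores are invariant to rescaling an input column", {
  set.seed(503)
  X <- matrix(runif(10 * 3, 0.5, 5), 10, 3)
  Y <- matrix(runif(10 * 2, 0.5, 5), 10, 2)
  base <- vapply(solve_all(dea_problem(X, Y, "input")),
                 `[[`, numeric(1), "rte")
  for (c_scale in c(0.01, 7, 1000)) {
    X2 <- X; X2[, 2] <- c_scale * X2[, 2]
    sc <- vapply(solve_all(dea_problem(X2, Y, "input")),
                 `[[`, numeric(1), "rte")
    expect_equal(sc, base, tolerance = 1e-7)
  }
})

test_that("frontier membership agrees across orientations", {
  set.seed(504)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    X <- matrix(runif(n * 2, 0.5, 4), n, 2)
    Y <- matrix(runif(n * 2, 0.5, 4), n, 2)
    rin <- vapply(solve_all(dea_problem(X, Y, "input")),
                  `[[`, numeric(1), "rte")
    rout <- vapply(solve_all(dea_problem(X, Y, "output")),
                   `[[`, numeric(1), "rte")
    expect_identical(abs(rin - 1) < 1e-6, abs(rout - 1) < 1e-6)
  }
})

test_that("envelopment scores match the independent multiplier-form oracle", {
  skip_if_not_installed("boot")
  set.seed(505)
  worst <- 0
  for (rep in 1:80) {
    n <- sample(2:5, 1); m <- sample(1:2, 1); s <- sample(1:2, 1)
    X <- matrix(runif(n * m, 0.2, 4), n, m)
    Y <- matrix(runif(n * s, 0.2, 4), n, s)
    mine <- vapply(solve_all(dea_problem(X, Y, "input")),
                   `[[`, numeric(1), "raw_objective")
    oracle <- vapply(seq_len(n), function(k) multiplier_vrs_input(X, Y, k),
                     numeric(1))
    worst <- max(worst, max(abs(mine - oracle)))
  }
  expect_lt(worst, 1e-6)
})

test_that("efficiency classification separates weak from full efficiency", {
  mk <- function(rte, slack) {
    structure(list(rte = rte, slack_total = slack), class = "dea_result")
  }
  expect_equal(classify(mk(1, 0)), "efficient")
  expect_equal(classify(mk(1, 0.3)), "weakly_efficient")
  expect_equal(classify(mk(0.5, 0)), "inefficient")
  # a weakly efficient unit arises from a real program: B matches A's
  # output with the same first input but wastes a second input
  X <- matrix(c(1, 1, 1, 2), 2, 2); Y <- matrix(c(1, 1), 2, 1)
  res <- solve_all(dea_problem(X, Y, "input"))
  expect_equal(res[[2]]$rte, 1)
  expect_equal(res[[2]]$input_slacks, c(0, 1), tolerance = 1e-7)
  expect_gt(res[[2]]$slack_total, 1e-6)
  expect_equal(res[[2]]$efficiency_class, "weakly_efficient")
})
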