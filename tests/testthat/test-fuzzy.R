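test_that("five-set partitions are a partition of unity with <= 2 active sets", {
  universes <- list(c(0, 1), c(0, 100), c(0.5, 3.7), c(-2, 5))
  for (u in universes) {
    p <- fuzzy_partition(u[1], u[2])
    x <- seq(u[1], u[2], length.out = 1e4)
    m <- fuzzify(x, p)
    expect_lt(max(abs(rowSums(m) - 1)), 1e-12)
    expect_lte(max(rowSums(m > 0)), 2)
  }
})

test_that("fuzzification handles peaks, midpoints and clamping", {
  p <- fuzzy_partition(0, 1)  # peaks at 0, .25, .5, .75, 1
  expect_equal(as.vector(fuzzify(0.5, p)), c(0, 0, 1, 0, 0))
  expect_equal(as.vector(fuzzify(0.375, p)), c(0, 0.5, 0.5, 0, 0))
  expect_equal(as.vector(fuzzify(-3, p)), c(1, 0, 0, 0, 0))
  expect_equal(as.vector(fuzzify(7, p)), c(0, 0, 0, 0, 1))
  expect_error(fuzzy_partition(1, 1), "degenerate universe")
})

test_that("product-sum gravity defuzzification matches hand centroids", {
  p <- fuzzy_partition(0, 1)
  # single interior set: its centroid is the peak (symmetric triangle)
  expect_equal(defuzzify(c(0, 0, 1, 0, 0), p), 0.5)
  # two equal-membership equal-area interior sets: midpoint of the peaks
  expect_equal(defuzzify(c(0, 0.5, 0.5, 0, 0), p), 0.375)
  expect_error(defuzzify(c(0, 0, 0, 0, 0), p), "all memberships are zero")
  # reconstruction between the interior-most peaks, brute-force scan
  xs <- seq(0.25, 0.75, length.out = 501)
  back <- defuzzify(fuzzify(xs, p), p)
  expect_lt(max(abs(back - xs)), 1e-12)
})

test_that("construct scores are bounded, anchored and monotone", {
  ds <- small_ecosystem()
  cfg <- default_fuzzy_config(ds)
  row <- ds$values[1, ]
  d_vars <- cfg$constructs$D$variables
  o_vars <- cfg$constructs$O$variables
  # all day-care provision at its universe max -> D = 100
  row_max <- row
  for (nm in d_vars) row_max[nm] <- cfg$constructs$D$universe[[nm]][2]
  expect_equal(unname(compute_constructs(row_max, cfg)["D"]), 100)
  # no outpatient provision -> O = 0
  row_zero <- row
  row_zero[o_vars] <- 0
  expect_equal(unname(compute_constructs(row_zero, cfg)["O"]), 0)
  sc <- compute_constructs(ds$values, cfg)
  expect_true(all(sc >= 0 & sc <= 100))
  # doubling one workforce variable never decreases the construct
  wf <- intersect(d_vars,
                  ds$variables$name[ds$variables$measure == "Prof"])[1]
  for (mult in c(1.2, 2, 5)) {
    row2 <- row
    row2[wf] <- mult * row2[wf]
    expect_gte(compute_constructs(row2, cfg)["D"],
               compute_constructs(row, cfg)["D"])
  }
})

test_that("rule-based displacement preserves the range width exactly", {
  ds <- small_ecosystem()
  cfg <- default_fuzzy_config(ds)
  set.seed(77)
  base <- list(x_left = 0.9753, x_right = 1.0979)
  for (i in 1:50) {
    sc <- c(D = runif(1, 0, 100), O = runif(1, 0, 100))
    adj <- adjust_range(base, sc, cfg, left_universe = c(0, 2))
    expect_equal(adj$x_right - adj$x_left, base$x_right - base$x_left,
                 tolerance = 1e-14)
  }
})

test_that("scarce day and outpatient provision displaces the range right", {
  ds <- small_ecosystem()
  cfg <- default_fuzzy_config(ds)
  # O "very little" (0), D "little" (score at the second peak, 25)
  scarce <- c(D = 25, O = 0)
  # abundant provision for contrast
  rich <- c(D = 100, O = 100)
  base <- list(x_left = 0.2, x_right = 0.4)
  lu <- c(0, 2)
  adj_scarce <- adjust_range(base, scarce, cfg, lu)
  adj_rich <- adjust_range(base, rich, cfg, lu)
  # consequent "much" sits right of the consequent "very little"
  expect_gt(adj_scarce$x_left, base$x_left)
  expect_gt(adj_scarce$x_left, adj_rich$x_left)
  # default rule table fires "much" for (D little, O very little)
  expect_equal(default_rule_base()[2, 1], 4L)
  expect_equal(default_rule_base()[1, 1], 5L)
  expect_equal(default_rule_base()[5, 5], 1L)
})

test_that("interpretation profiles follow their printed arithmetic", {
  # literal profile: width minus the value
  expect_equal(interpret_value(0.9753, 0.9753, 1.0979, "centred_literal"),
               (1.0979 - 0.9753) - 0.9753)
  expect_equal(interpret_value(c(1, 2, 3), 0, 1, "identity"), c(1, 2, 3))
  # tent profile: distance from the range centre
  expect_equal(interpret_value(0.5, 0.2, 0.8, "centre_distance"), 0)
  expect_equal(interpret_value(0.9, 0.2, 0.8, "centre_distance"), 0.4)
  # monotone within each linear piece, for every profile
  xl <- 0.4; xr <- 0.9; ctr <- (xl + xr) / 2
  pieces <- list(seq(0, xl, length.out = 50),
                 seq(xl, ctr, length.out = 50),
                 seq(ctr, xr, length.out = 50),
                 seq(xr, 2, length.out = 50))
  for (prof in c("identity", "centred_literal", "centre_distance")) {
    for (xs in pieces) {
      y <- interpret_value(xs, xl, xr, prof)
      expect_true(all(diff(y) >= -1e-12) || all(diff(y) <= 1e-12),
                  info = prof)
    }
  }
  expect_error(interpret_value(1, 2, 1, "identity"), "invalid range")
})

test_that("dataset interpretation passes through unconfigured columns", {
  ds <- small_ecosystem()
  cfg <- default_fuzzy_config(ds)
  S <- ds$values
  I <- interpret_dataset(S, cfg)
  conf <- names(cfg$interpretation)
  expect_identical(I[, setdiff(colnames(S), conf)],
                   S[, setdiff(colnames(S), conf)])
  expect_false(identical(I[, conf], S[, conf]))
  # identity profiles reproduce the input exactly
  cfg_id <- cfg
  for (nm in names(cfg_id$interpretation)) {
    cfg_id$interpretation[[nm]]$profile <- "identity"
    cfg_id$interpretation[[nm]]$adjust <- FALSE
  }
  expect_identical(interpret_dataset(S, cfg_id), S)
  # deterministic
  expect_identical(interpret_dataset(S, cfg), interpret_dataset(S, cfg))
})

test_that("fuzzy configuration round-trips through YAML", {
  ds <- small_ecosystem()
  cfg <- default_fuzzy_config(ds)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_fuzzy_config(cfg, f)
  cfg2 <- read_fuzzy_config(f)
  expect_identical(cfg2$rules, cfg$rules)
  expect_equal(cfg2$constructs$D$variables, cfg$constructs$D$variables)
  S <- ds$values
  expect_equal(interpret_dataset(S, cfg2), interpret_dataset(S, cfg),
               tolerance = 1e-12)
})
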