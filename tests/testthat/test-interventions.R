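test_that("interventions edit exactly the listed cells", {
  ds <- small_ecosystem()
  empty <- intervention_spec("I0", "nothing", data.frame())
  expect_identical(apply_intervention(ds, empty)$values, ds$values)
  # paired reassignment conserves the column total
  v <- "ProfTotO8+O10"
  spec <- intervention_spec("I1", "shift", data.frame(
    dmu = ds$dmu_names[c(1, 3)], variable = v,
    change = c(-2, 2), stringsAsFactors = FALSE))
  post <- apply_intervention(ds, spec)
  expect_equal(sum(post$values[, v]), sum(ds$values[, v]))
  diff_cells <- which(post$values != ds$values, arr.ind = TRUE)
  expect_equal(nrow(diff_cells), 2)
  expect_setequal(rownames(post$values)[diff_cells[, 1]],
                  ds$dmu_names[c(1, 3)])
  # an N-edit spec changes exactly N cells
  spec4 <- generate_intervention(ds, n_edits = 4, seed = 5)
  post4 <- apply_intervention(ds, spec4)
  expect_equal(sum(post4$values != ds$values), 4)
})

test_that("interventions cannot drive cells negative and name the cell", {
  ds <- small_ecosystem()
  v <- "ProfTotO8+O10"
  bad <- intervention_spec("Ibad", "", data.frame(
    dmu = ds$dmu_names[1], variable = v,
    change = -(ds$values[1, v] + 1), stringsAsFactors = FALSE))
  expect_error(apply_intervention(ds, bad), "negative")
  expect_error(apply_intervention(ds, intervention_spec(
    "Iunk", "", data.frame(dmu = "nowhere", variable = v, change = 1))),
    "unknown cell")
  expect_error(intervention_spec("Idir", "", data.frame(
    dmu = "A", variable = v, change = 1, direction = "decreasing")),
    "contradicts")
})

test_that("count-mode edits convert head counts with the population", {
  ds <- small_ecosystem()
  v <- "ProfTotO8+O10"
  pop <- setNames(rep(50000, 19), ds$dmu_names)
  spec <- intervention_spec("Ic", "", data.frame(
    dmu = ds$dmu_names[1], variable = v, change = 1, mode = "count",
    stringsAsFactors = FALSE))
  post <- apply_intervention(ds, spec, population = pop)
  expect_equal(post$values[1, v] - ds$values[1, v], 1e5 * 1 / 50000)
  expect_error(apply_intervention(ds, spec), "population")
})

test_that("variation percentages follow the pre/post convention", {
  expect_equal(round(variation_pct(0.7831, 0.7857), 2), 0.33)
  expect_equal(variation_pct(2, 1), -50)
  expect_warning(v0 <- variation_pct(0, 1), "undefined")
  expect_true(is.na(v0))
  # antisymmetry up to the denominator change
  expect_equal(sign(variation_pct(1, 2)), -sign(variation_pct(2, 1)))
})

test_that("identical pools compare as unchanged and indistinguishable", {
  set.seed(701)
  n <- 400
  cls <- sample(c("inefficient", "efficient"), n, TRUE, c(0.8, 0.2))
  pool <- rte_pool("d", "s", seq_len(n), "input",
                   ifelse(cls == "inefficient", runif(n, 0.3, 0.999), 1),
                   0, cls)
  rep <- compare_pools(pool, pool)
  expect_true(all(rep$stats$variation_pct == 0, na.rm = TRUE))
  expect_false(rep$tests$ks$reject[["alpha_0.05"]])
  expect_false(rep$tests$t$reject[["alpha_0.05"]])
})

test_that("a constructed mean shift is detected by t but not by Levene", {
  set.seed(702)
  n <- 2000
  pre_scores <- runif(n, 0.30, 0.90)
  post_scores <- pre_scores + 0.05   # pure location shift, same spread
  pre <- rte_pool("d", "s", seq_len(n), "input", pre_scores, 0,
                  "inefficient")
  post <- rte_pool("d", "s", seq_len(n), "input", post_scores, 0,
                   "inefficient")
  rep <- compare_pools(pre, post)
  expect_true(rep$tests$t$reject[["alpha_0.05"]])
  expect_false(rep$tests$levene$reject[["alpha_0.05"]])
  expect_equal(rep$stats$variation_pct[rep$stats$statistic == "mean"],
               100 * 0.05 / mean(pre_scores), tolerance = 1e-9)
})

test_that("the Levene implementation matches the reference one", {
  skip_if_not_installed("car")
  set.seed(703)
  x <- c(rnorm(100, 0, 1), rnorm(120, 0, 1.8))
  g <- rep(c("a", "b"), c(100, 120))
  mine <- rtesim:::levene_test(x, g)
  ref <- car::leveneTest(x, factor(g), center = mean)
  expect_equal(mine$statistic, ref[1, "F value"], tolerance = 1e-9)
  expect_equal(mine$p.value, ref[1, "Pr(>F)"], tolerance = 1e-9)
})

test_that("comparison export uses the Pre / Post / Variation layout", {
  set.seed(704)
  pool <- rte_pool("d", "s", 1:50, "input", runif(50, 0.2, 0.99), 0,
                   "inefficient")
  f <- withr::local_tempfile(fileext = ".csv")
  write_comparison(compare_pools(pool, pool), f)
  hdr <- names(utils::read.csv(f, check.names = FALSE))
  expect_equal(hdr, c("Results", "Pre-Interventions",
                      "Post-Interventions", "Variation (%)"))
})

test_that("intervention specs round-trip through YAML", {
  ds <- small_ecosystem()
  spec <- generate_intervention(ds, n_edits = 4, seed = 9)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_intervention(spec, f)
  spec2 <- load_intervention(f)
  expect_equal(spec2$id, spec$id)
  expect_equal(nrow(spec2$edits), 4)
  expect_equal(as.numeric(spec2$edits$change), spec$edits$change,
               tolerance = 1e-9)
})
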