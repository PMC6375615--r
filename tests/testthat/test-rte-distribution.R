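test_that("binning follows the 22-interval scheme", {
  one <- function(rte, cls, slack = if (cls == "weakly_efficient") 1 else 0)
    rte_pool("d", "s", 1, "input", rte, slack, cls)
  h <- bin_pool(one(0.02, "inefficient"))
  expect_equal(h$freq[1], 1)
  expect_equal(sum(h$freq), 1)
  h21 <- bin_pool(one(1, "weakly_efficient"))
  expect_equal(h21$freq[21], 1)
  h22 <- bin_pool(one(1, "efficient"))
  expect_equal(h22$freq[22], 1)
  # half-open edges: 0.05 belongs to the second interval
  h2 <- bin_pool(one(0.05, "inefficient"))
  expect_equal(h2$freq[2], 1)
  expect_error(bin_pool(one(0.5, "inefficient")[0, ]), "empty pool")
  # frequencies always sum to one on random pools
  set.seed(601)
  for (i in 1:10) {
    n <- sample(10:200, 1)
    cls <- sample(c("inefficient", "weakly_efficient", "efficient"),
                  n, replace = TRUE)
    p <- rte_pool("d", "s", seq_len(n), "input",
                  ifelse(cls == "inefficient", runif(n, 0, 0.9999), 1),
                  ifelse(cls == "weakly_efficient", 1, 0), cls)
    expect_equal(sum(bin_pool(p)$freq), 1)
  }
})

test_that("estimator suite partitions probability and counts thresholds", {
  eff <- rte_pool("d", "s", 1:10, "input", rep(1, 10), 0, "efficient")
  e <- estimators(eff)
  expect_equal(e$p_efficient, 1)
  expect_equal(e$mean, 1)
  expect_equal(e$sd, 0)
  p <- rte_pool("d", "s", 1:4, "input", c(0.2, 0.4, 0.6, 0.8), 0,
                "inefficient")
  expect_equal(estimators(p, above = 0.75)$p_above, 0.25)
  expect_equal(estimators(p, range = c(0.3, 0.7))$p_range, 0.5)
  set.seed(602)
  for (i in 1:10) {
    n <- sample(5:100, 1)
    cls <- sample(c("inefficient", "weakly_efficient", "efficient"),
                  n, replace = TRUE)
    pool <- rte_pool("d", "s", seq_len(n), "input",
                     ifelse(cls == "inefficient", runif(n, 0, 0.999), 1),
                     ifelse(cls == "weakly_efficient", 1, 0), cls)
    e <- estimators(pool)
    expect_equal(e$p_efficient + e$p_weak + e$p_inefficient, 1)
  }
})

test_that("interval stability anchors at one interval and all intervals", {
  mk_hist <- function(freq) structure(list(freq = freq, n = 100,
                                           inttot = length(freq)),
                                      class = "rte_histogram")
  f5 <- example_e_freq()
  expect_equal(interval_stability(mk_hist(f5)), 100 - 100 * 4 / 21)
  f1 <- c(1, numeric(21))
  expect_equal(interval_stability(mk_hist(f1)), 100)
  f22 <- rep(1 / 22, 22)
  expect_equal(interval_stability(mk_hist(f22)), 0)
})

test_that("density stability accumulates descending frequencies", {
  mk_hist <- function(freq) structure(list(freq = freq, n = 100,
                                           inttot = length(freq)),
                                      class = "rte_histogram")
  d <- density_stability(mk_hist(example_e_freq()))
  expect_equal(d$acprob, 0.88)
  expect_equal(d$nintprob, 3)
  expect_equal(d$denstab,
               100 * (log(0.88 * 100 / 3) - 1.2909) / (4.6051 - 1.2909),
               tolerance = 1e-12)
  # all mass in one interval is completely stable
  expect_equal(density_stability(mk_hist(c(1, numeric(21))))$denstab, 100)
  # an accumulation ratio exactly at the lower anchor scores zero:
  # uniform over 22 bins crosses 0.8 at 18 bins, ratio (18/22)*100/18
  params0 <- stability_params(minln = log(100 / 22))
  expect_equal(density_stability(mk_hist(rep(1 / 22, 22)),
                                 params0)$denstab, 0)
})

test_that("the printed logarithm anchors match their closed forms", {
  p <- stability_params(derive_ln = TRUE)
  expect_equal(p$minln, log(100 * 0.8 / 22))
  expect_equal(p$maxln, log(100))
  expect_lt(abs(p$minln - 1.2909), 2e-4)
  expect_lt(abs(p$maxln - 4.6051), 2e-4)
})

test_that("weighted stability is the configured convex combination", {
  expect_equal(weighted_stability(80.95, 63.13), 72.04)
  expect_equal(weighted_stability(80.95, 63.13,
                                  stability_params(w_int = 1, w_den = 0)),
               80.95)
  expect_equal(weighted_stability(80.95, 63.13,
                                  stability_params(w_int = 0, w_den = 0)),
               0)
})

test_that("entropy is zero when concentrated and maximal when uniform", {
  mk_hist <- function(freq) structure(list(freq = freq, n = 100,
                                           inttot = length(freq)),
                                      class = "rte_histogram")
  expect_equal(shannon_entropy(mk_hist(c(1, numeric(21))))$entropy, 0)
  expect_equal(shannon_entropy(mk_hist(c(0.5, 0.5, numeric(20))))$entropy, 1)
  u <- shannon_entropy(mk_hist(rep(1 / 22, 22)))
  expect_equal(u$entropy, log2(22), tolerance = 1e-12)
  expect_equal(u$pct_of_max, 100, tolerance = 1e-12)
  # any non-uniform histogram has strictly lower entropy
  set.seed(603)
  for (i in 1:10) {
    f <- runif(22); f <- f / sum(f)
    if (max(abs(f - 1 / 22)) < 1e-6) next
    expect_lt(shannon_entropy(mk_hist(f))$entropy, log2(22))
  }
})

test_that("indicators depend on frequencies only, not bin positions", {
  mk_hist <- function(freq) structure(list(freq = freq, n = 100,
                                           inttot = length(freq)),
                                      class = "rte_histogram")
  f <- example_e_freq()
  set.seed(604)
  for (i in 1:5) {
    g <- f[sample(22)]
    expect_equal(interval_stability(mk_hist(g)),
                 interval_stability(mk_hist(f)))
    expect_equal(density_stability(mk_hist(g))$denstab,
                 density_stability(mk_hist(f))$denstab)
    expect_equal(shannon_entropy(mk_hist(g))$entropy,
                 shannon_entropy(mk_hist(f))$entropy)
  }
  # merging mass into fewer intervals never decreases interval stability
  merged <- f
  merged[18] <- merged[18] + merged[10]; merged[10] <- 0
  expect_gte(interval_stability(mk_hist(merged)),
             interval_stability(mk_hist(f)))
})

test_that("stability report bundles all indicators coherently", {
  pool <- fig_style_pool(example_e_freq(), 100)
  rep <- stability_report(bin_pool(pool))
  expect_equal(rep$nint, 5)
  expect_equal(rep$acprob, 0.88)
  expect_equal(rep$nintprob, 3)
  expect_equal(rep$stab,
               0.5 * rep$intstab + 0.5 * rep$denstab)
  expect_true(rep$entropy >= 0 && rep$entropy <= log2(22))
})
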