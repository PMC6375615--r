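#' RTE score pools
#'
#' A pool is the stored collection of simulated relative-technical-
#' efficiency scores: one record per (DMU, scenario, simulation,
#' orientation) with the score, its residual slack total and the
#' efficiency class.
#'
#' @param dmu,scenario,simulation,orientation,rte,slack_total,class
#'   vectors of equal length (recycled where sensible).
#' @return A `data.frame` of class `rte_pool`.
#' @export
rte_pool <- function(dmu, scenario, simulation, orientation, rte,
                     slack_total, class) {
  df <- data.frame(dmu = dmu, scenario = scenario,
                   simulation = simulation, orientation = orientation,
                   rte = rte, slack_total = slack_total, class = class,
                   stringsAsFactors = FALSE)
  validate_pool(df)
  structure(df, class = c("rte_pool", "data.frame"))
}

validate_pool <- function(df) {
  req <- c("dmu", "scenario", "simulation", "orientation", "rte",
           "slack_total", "class")
  if (!all(req %in% names(df)))
    stop("pool must have columns: ", paste(req, collapse = ", "))
  if (any(df$rte < 0 | df$rte > 1 + 1e-9))
    stop("rte scores must lie in [0, 1]")
  if (!all(df$class %in% c("efficient", "weakly_efficient", "inefficient")))
    stop("unknown efficiency class")
  invisible(df)
}

#' @export
as.data.frame.rte_pool <- function(x, ...) {
  class(x) <- "data.frame"
  x
}

#' 22-interval frequency analysis of an RTE pool
#'
#' Inefficient scores are binned into 20 half-open intervals
#' `[0, 0.05), [0.05, 0.1), ..., [0.95, 1)`; weakly efficient records
#' (score 1, nonzero slack) fall into bin 21 and fully efficient
#' records into bin 22. With a non-default `inttot`, `inttot - 2` score
#' bins of equal width are used ahead of the two efficiency bins.
#'
#' @param pool an `rte_pool` (or data.frame with `rte` and `class`),
#'   already filtered to one unit of analysis.
#' @param inttot total number of intervals (default 22).
#' @return An `rte_histogram`: relative frequencies `freq` (length
#'   `inttot`, summing to 1), `counts`, and the pool size `n`.
#' @export
bin_pool <- function(pool, inttot = 22) {
  if (NROW(pool) == 0) stop("empty pool")
  if (inttot < 3) stop("need at least 3 intervals")
  nscore <- inttot - 2
  counts <- integer(inttot)
  eff <- pool$class == "efficient"
  weak <- pool$class == "weakly_efficient"
  ineff <- !eff & !weak
  counts[inttot] <- sum(eff)
  counts[inttot - 1] <- sum(weak)
  if (any(ineff)) {
    idx <- pmin(floor(pool$rte[ineff] * nscore) + 1L, nscore)
    tab <- tabulate(idx, nbins = nscore)
    counts[seq_len(nscore)] <- tab
  }
  n <- sum(counts)
  structure(list(freq = counts / n, counts = counts, n = n,
                 inttot = inttot),
            class = "rte_histogram")
}

#' @export
print.rte_histogram <- function(x, ...) {
  cat("<rte_histogram> n =", x$n, ", populated intervals:",
      sum(x$freq > 0), "of", x$inttot, "\n")
  invisible(x)
}

#' Estimator suite for an RTE pool
#'
#' Class probabilities come from the efficiency-class counts; mean and
#' standard deviation from the raw scores. The "efficiency error" is
#' reported as a configurable multiple of the standard deviation
#' (default factor 1, i.e. the standard deviation itself), with
#' `error_pct` the error as a percentage of the mean.
#'
#' @param pool an `rte_pool` filtered to one unit of analysis.
#' @param above threshold for `p_above` = P(RTE > above).
#' @param range optional `c(a, b)` for `p_range` = P(a < RTE < b).
#' @param error_factor multiplier applied to the standard deviation.
#' @return A list of class `estimator_report`.
#' @export
estimators <- function(pool, above = 0.75, range = NULL,
                       error_factor = 1) {
  if (NROW(pool) == 0) stop("empty pool")
  n <- NROW(pool)
  p_eff <- sum(pool$class == "efficient") / n
  p_weak <- sum(pool$class == "weakly_efficient") / n
  p_ineff <- sum(pool$class == "inefficient") / n
  mu <- mean(pool$rte)
  sdev <- stats::sd(pool$rte)
  if (is.na(sdev)) sdev <- 0
  err <- error_factor * sdev
  rep <- list(p_efficient = p_eff, p_weak = p_weak,
              p_inefficient = p_ineff,
              mean = mu, sd = sdev, error = err,
              error_pct = if (mu > 0) 100 * err / mu else NA_real_,
              p_above = sum(pool$rte > above) / n,
              above = above)
  if (!is.null(range)) {
    rep$p_range <- sum(pool$rte > range[1] & pool$rte < range[2]) / n
    rep$range <- range
  }
  structure(rep, class = "estimator_report")
}

#' Stability parameters
#'
#' Defaults mirror the reference configuration of the 22-interval
#' frequency analysis: accumulation threshold `prob = 0.8` and
#' logarithm anchors `minln = 1.2909`, `maxln = 4.6051`. The anchors
#' satisfy the closed forms `minln = ln(100 * prob / inttot)` and
#' `maxln = ln(100)` (to the printed precision); `derive_ln = TRUE`
#' recomputes them from `prob` and `inttot` instead of using the fixed
#' constants.
#'
#' @param inttot total interval count.
#' @param prob accumulation threshold in (0, 1).
#' @param minln,maxln logarithm anchors for the density indicator.
#' @param w_int,w_den non-negative weights of the two components.
#' @param derive_ln derive `minln`/`maxln` from `prob` and `inttot`.
#' @return A list of class `stability_params`.
#' @export
stability_params <- function(inttot = 22, prob = 0.8, minln = 1.2909,
                             maxln = 4.6051, w_int = 0.5, w_den = 0.5,
                             derive_ln = FALSE) {
  if (!(prob > 0 && prob < 1)) stop("prob must be in (0, 1)")
  if (inttot < 2) stop("inttot must be >= 2")
  if (w_int < 0 || w_den < 0) stop("weights must be non-negative")
  if (derive_ln) {
    minln <- log(100 * prob / inttot)
    maxln <- log(100)
  }
  if (!(minln < maxln)) stop("need minln < maxln")
  structure(list(inttot = inttot, prob = prob, minln = minln,
                 maxln = maxln, w_int = w_int, w_den = w_den),
            class = "stability_params")
}

#' Stability and entropy indicators of an RTE distribution
#'
#' `interval_stability()` measures how few histogram intervals carry
#' probability: `100 - 100 * (nint - 1) / (inttot - 1)`, where `nint`
#' counts intervals with positive frequency (100 = all mass in one
#' interval, 0 = every interval populated).
#'
#' `density_stability()` measures probability concentration:
#' frequencies are accumulated in descending order until the running
#' sum first strictly exceeds `prob`; with `acprob` that sum and
#' `nintprob` the number of intervals used,
#' `denstab = 100 * (ln(100 * acprob / nintprob) - minln) / (maxln - minln)`,
#' clamped into `[0, 100]` (the fixed anchors are printed at 4 decimals
#' so the unclamped value can exceed 100 by about 0.002 when all mass
#' sits in one interval). Ties between equally frequent intervals are
#' resolved toward the higher-efficiency interval.
#'
#' `weighted_stability()` combines the two components:
#' `w_int * intstab + w_den * denstab`.
#'
#' `shannon_entropy()` is the base-2 entropy of the frequencies (with
#' `0 log 0 := 0`) and its percentage of the maximum `log2(inttot)`.
#'
#' @param h an `rte_histogram` from [bin_pool()].
#' @param params a [stability_params()].
#' @return `interval_stability()`: a number in `[0, 100]`.
#'   `density_stability()`: list `denstab`, `acprob`, `nintprob`.
#'   `weighted_stability()`: a number. `shannon_entropy()`: list
#'   `entropy` (bits), `pct_of_max`.
#' @export
interval_stability <- function(h, params = stability_params()) {
  nint <- sum(h$freq > 0)
  100 - 100 * (nint - 1) / (params$inttot - 1)
}

#' @rdname interval_stability
#' @export
density_stability <- function(h, params = stability_params()) {
  freq <- h$freq
  ord <- order(-freq, -seq_along(freq))
  cum <- cumsum(freq[ord])
  nintprob <- which(cum > params$prob)[1]
  if (is.na(nintprob))
    stop("accumulated probability never exceeds prob = ", params$prob)
  acprob <- cum[nintprob]
  arg <- acprob * 100 / nintprob
  if (arg <= 0) stop("non-positive logarithm argument")
  denstab <- 100 * (log(arg) - params$minln) / (params$maxln - params$minln)
  list(denstab = min(max(denstab, 0), 100),
       acprob = acprob, nintprob = nintprob)
}

#' @rdname interval_stability
#' @param intstab,denstab component values on the 0-100 scale.
#' @export
weighted_stability <- function(intstab, denstab,
                               params = stability_params()) {
  params$w_int * intstab + params$w_den * denstab
}

#' @rdname interval_stability
#' @export
shannon_entropy <- function(h) {
  f <- h$freq[h$freq > 0]
  entropy <- -sum(f * log2(f))
  list(entropy = entropy,
       pct_of_max = 100 * entropy / log2(h$inttot))
}

#' Full stability report for one RTE distribution
#'
#' @param h an `rte_histogram`.
#' @param params a [stability_params()].
#' @return A list of class `stability_report` with `nint`, `acprob`,
#'   `nintprob`, `intstab`, `denstab`, `stab`, `entropy`,
#'   `entropy_pct_of_max`.
#' @export
stability_report <- function(h, params = stability_params()) {
  intstab <- interval_stability(h, params)
  dens <- density_stability(h, params)
  ent <- shannon_entropy(h)
  structure(list(nint = sum(h$freq > 0),
                 acprob = dens$acprob, nintprob = dens$nintprob,
                 intstab = intstab, denstab = dens$denstab,
                 stab = weighted_stability(intstab, dens$denstab, params),
                 entropy = ent$entropy,
                 entropy_pct_of_max = ent$pct_of_max),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(paste0("<stability_report> intstab = %.2f, denstab = %.2f, ",
                     "stab = %.2f, entropy = %.2f bits (%.2f%% of max)\n"),
              x$intstab, x$denstab, x$stab, x$entropy,
              x$entropy_pct_of_max))
  invisible(x)
}
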