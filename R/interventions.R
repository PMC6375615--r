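#' Management intervention specifications
#'
#' A management intervention is a planned resource shift (availability,
#' placement or workforce capacity) encoded as a list of cell edits on
#' the dataset: each edit names a DMU, a variable, a signed change and a
#' direction tag. Secondary "causal" edits (e.g. a shared day hospital
#' serving several areas) are never inferred; they must be listed
#' explicitly.
#'
#' @param id short identifier.
#' @param description free text.
#' @param edits `data.frame` with columns `dmu`, `variable`, `change`
#'   (signed amount), optional `mode` (`"rate"`: the change is already a
#'   rate per 100,000; `"count"`: a head/bed count converted with the
#'   DMU's population at application time) and optional `direction`
#'   (`"increasing"`/`"decreasing"`, checked against the sign).
#' @return An `intervention_spec` object.
#' @export
intervention_spec <- function(id, description = "", edits) {
  if (NROW(edits) == 0) {
    edits <- data.frame(dmu = character(), variable = character(),
                        change = numeric(), mode = character(),
                        direction = character(), stringsAsFactors = FALSE)
  }
  if (!all(c("dmu", "variable", "change") %in% names(edits)))
    stop("edits need columns dmu, variable, change")
  if (is.null(edits$mode)) edits$mode <- "rate"
  if (is.null(edits$direction))
    edits$direction <- ifelse(edits$change >= 0, "increasing", "decreasing")
  bad <- (edits$change > 0 & edits$direction == "decreasing") |
         (edits$change < 0 & edits$direction == "increasing")
  if (any(bad))
    stop("edit direction tag contradicts the sign of the change: ",
         paste(edits$dmu[bad], edits$variable[bad], sep = "/",
               collapse = ", "))
  structure(list(id = id, description = description, edits = edits),
            class = "intervention_spec")
}

#' @export
print.intervention_spec <- function(x, ...) {
  cat("<intervention_spec> ", x$id, ": ", nrow(x$edits), " cell edits\n",
      sep = "")
  invisible(x)
}

#' Read / write intervention specifications (YAML)
#'
#' @param path YAML file path.
#' @return `load_intervention()` returns an `intervention_spec`.
#' @export
load_intervention <- function(path) {
  raw <- yaml::read_yaml(path)
  edits <- do.call(rbind, lapply(raw$edits, function(e) {
    data.frame(dmu = e$dmu, variable = e$variable,
               change = as.numeric(e$change),
               mode = e$mode %||% "rate",
               direction = e$direction %||%
                 (if (e$change >= 0) "increasing" else "decreasing"),
               stringsAsFactors = FALSE)
  }))
  intervention_spec(raw$id, raw$description %||% "", edits)
}

#' @rdname load_intervention
#' @param spec an `intervention_spec`.
#' @export
write_intervention <- function(spec, path) {
  edits_list <- lapply(seq_len(nrow(spec$edits)), function(i)
    as.list(spec$edits[i, ]))
  yaml::write_yaml(list(id = spec$id, description = spec$description,
                        edits = edits_list),
                   path, precision = 15)
  invisible(path)
}

#' Apply an intervention to a dataset
#'
#' Exactly the listed cells change, by the stated amounts; everything
#' else is untouched. Edits in `"count"` mode are converted to rates
#' with the DMU's population (`rate change = 100000 * count /
#' population`). Any downstream randomization plan must be rebuilt from
#' the edited dataset so the cell distributions reflect the new values.
#'
#' @param ds an `ecosystem_dataset`.
#' @param spec an `intervention_spec`.
#' @param population named numeric vector (inhabitants per DMU),
#'   required only for `"count"`-mode edits.
#' @return The edited `ecosystem_dataset`.
#' @export
apply_intervention <- function(ds, spec, population = NULL) {
  stopifnot(inherits(ds, "ecosystem_dataset"),
            inherits(spec, "intervention_spec"))
  vals <- ds$values
  e <- spec$edits
  if (nrow(e) == 0) return(ds)
  i <- match(e$dmu, ds$dmu_names)
  j <- match(e$variable, ds$variables$name)
  bad <- is.na(i) | is.na(j)
  if (any(bad))
    stop("edit references unknown cell(s): ",
         paste(e$dmu[bad], e$variable[bad], sep = "/", collapse = ", "))
  delta <- e$change
  cnt <- e$mode == "count"
  if (any(cnt)) {
    if (is.null(population))
      stop("count-mode edits require a population vector")
    pop <- population[e$dmu[cnt]]
    if (anyNA(pop))
      stop("missing population for: ",
           paste(unique(e$dmu[cnt][is.na(pop)]), collapse = ", "))
    delta[cnt] <- 1e5 * delta[cnt] / pop
  }
  idx <- cbind(i, j)
  newv <- vals[idx] + delta
  neg <- newv < 0
  if (any(neg))
    stop("edit drives cell(s) negative: ",
         paste(e$dmu[neg], e$variable[neg], sep = "/", collapse = ", "))
  vals[idx] <- newv
  ecosystem_dataset(vals, ds$variables, ds$dmu_names)
}

#' Percentage variation between a pre and a post value
#'
#' `100 * (post - pre) / pre`; `NA` (with a warning) when `pre` is 0.
#'
#' @param pre,post numeric vectors.
#' @return Numeric vector of percentages.
#' @export
variation_pct <- function(pre, post) {
  out <- ifelse(pre == 0, NA_real_, 100 * (post - pre) / pre)
  if (any(pre == 0))
    warning("variation undefined where the pre value is 0")
  out
}

# Levene's test for homogeneity of variances (classic, mean-centred):
# one-way ANOVA on the absolute deviations from the group mean.
levene_test <- function(x, g) {
  g <- factor(g)
  dev <- abs(x - stats::ave(x, g))
  fit <- stats::aov(dev ~ g)
  s <- summary(fit)[[1]]
  list(statistic = s[["F value"]][1], p.value = s[["Pr(>F)"]][1])
}

#' Compare pre- and post-intervention RTE pools
#'
#' Computes the estimator suite (see [estimators()]) and the stability
#' and entropy indicators for both pools, their percentage variations,
#' and three tests of the pre/post difference: a two-sample t-test
#' (Welch's version whenever Levene's test rejects variance equality at
#' the 0.05 level), Levene's test for equality of variances, and the
#' two-sample Kolmogorov-Smirnov test, each reported with accept/reject
#' decisions at the 0.05 and 0.01 levels.
#'
#' @param pre,post `rte_pool`s computed with identical configuration
#'   apart from the intervention, filtered to the same unit of
#'   analysis.
#' @param params a [stability_params()].
#' @param above threshold for the `p_above` estimator.
#' @param error_factor see [estimators()].
#' @param alpha significance levels reported.
#' @return A `comparison_report`: `stats` data.frame (statistic, pre,
#'   post, variation_pct) and `tests` list.
#' @export
compare_pools <- function(pre, post, params = stability_params(),
                          above = 0.75, error_factor = 1,
                          alpha = c(0.05, 0.01)) {
  if (NROW(pre) == 0 || NROW(post) == 0) stop("empty pool")
  est_pre <- estimators(pre, above = above, error_factor = error_factor)
  est_post <- estimators(post, above = above, error_factor = error_factor)
  st_pre <- stability_report(bin_pool(pre, params$inttot), params)
  st_post <- stability_report(bin_pool(post, params$inttot), params)
  keys <- c("p_efficient", "p_weak", "p_inefficient", "mean", "sd",
            "error", "p_above")
  skeys <- c("intstab", "denstab", "stab", "entropy")
  pre_v <- c(unlist(est_pre[keys]), unlist(st_pre[skeys]))
  post_v <- c(unlist(est_post[keys]), unlist(st_post[skeys]))
  stats_df <- data.frame(statistic = c(keys, skeys),
                         pre = pre_v, post = post_v,
                         variation_pct = suppressWarnings(
                           variation_pct(pre_v, post_v)),
                         row.names = NULL, stringsAsFactors = FALSE)
  lev <- levene_test(c(pre$rte, post$rte),
                     rep(c("pre", "post"), c(nrow(pre), nrow(post))))
  # degenerate pools (e.g. an always-efficient DMU) have zero variance;
  # the location test is then vacuous and reported as such
  tt <- tryCatch(
    stats::t.test(pre$rte, post$rte,
                  var.equal = isTRUE(lev$p.value >= 0.05)),
    error = function(e) list(statistic = NA_real_, p.value = NA_real_))
  ks <- suppressWarnings(stats::ks.test(pre$rte, post$rte))
  decide <- function(p) setNames(!is.na(p) & p < alpha,
                                 paste0("alpha_", alpha))
  structure(list(stats = stats_df,
                 tests = list(
                   t = list(statistic = unname(tt$statistic),
                            p.value = tt$p.value,
                            welch = isTRUE(lev$p.value < 0.05),
                            reject = decide(tt$p.value)),
                   levene = list(statistic = lev$statistic,
                                 p.value = lev$p.value,
                                 reject = decide(lev$p.value)),
                   ks = list(statistic = unname(ks$statistic),
                             p.value = ks$p.value,
                             reject = decide(ks$p.value))),
                 n_pre = nrow(pre), n_post = nrow(post)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> n_pre =", x$n_pre, ", n_post =", x$n_post, "\n")
  print(transform(x$stats, pre = signif(pre, 4), post = signif(post, 4),
                  variation_pct = round(variation_pct, 2)))
  cat(sprintf("t: p = %.4g | Levene: p = %.4g | KS: p = %.4g\n",
              x$tests$t$p.value, x$tests$levene$p.value,
              x$tests$ks$p.value))
  invisible(x)
}

#' Export a comparison report as a Pre / Post / Variation table
#'
#' @param report a `comparison_report`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(report, path) {
  df <- report$stats
  names(df) <- c("Results", "Pre-Interventions", "Post-Interventions",
                 "Variation (%)")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
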