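#' Pipeline configuration
#'
#' Bundles everything one Monte-Carlo efficiency run needs: the number
#' of simulations per scenario, the scenario list, the orientations,
#' the randomization weights and cell overrides, the fuzzy
#' configuration and the root seed. The reference study configuration
#' is 500 simulations, 15 scenarios, both orientations.
#'
#' Seeding: one root seed deterministically spawns a substream seed per
#' (simulation, scenario) pair, so runs are exactly reproducible and
#' scenario-level parallelization would not change results. Both
#' orientations are solved on the same sampled realization, so
#' input/output comparisons are paired.
#'
#' @param scenarios named list of `scenario_spec`s.
#' @param n_sim simulations per scenario (and DMU), `>= 1`.
#' @param orientations subset of `c("input", "output")`.
#' @param weights randomization weights (`w_tl`, `w_tr`, `w_ur`).
#' @param uniform_cells,fixed_cells cell overrides for [build_plan()].
#' @param fuzzy a `fuzzy_config`, or `NULL` to derive the default from
#'   the dataset at run time, or `FALSE` to skip interpretation.
#' @param stability a [stability_params()].
#' @param seed root integer seed.
#' @param input_floor floor for non-positive inputs in the DEA stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(scenarios, n_sim = 500,
                            orientations = c("input", "output"),
                            weights = list(w_tl = 0.9, w_tr = 1.1,
                                           w_ur = 1.1),
                            uniform_cells = NULL, fixed_cells = NULL,
                            fuzzy = NULL,
                            stability = stability_params(),
                            seed = 1, input_floor = 1e-9) {
  orientations <- match.arg(orientations, c("input", "output"),
                            several.ok = TRUE)
  if (n_sim < 1) stop("n_sim must be >= 1")
  if (length(scenarios) == 0) stop("at least one scenario is required")
  structure(list(scenarios = scenarios, n_sim = as.integer(n_sim),
                 orientations = orientations, weights = weights,
                 uniform_cells = uniform_cells,
                 fixed_cells = fixed_cells, fuzzy = fuzzy,
                 stability = stability, seed = as.integer(seed),
                 input_floor = input_floor),
            class = "pipeline_config")
}

#' Run the Monte-Carlo efficiency pipeline
#'
#' For every simulation and scenario: draw one randomized realization
#' of the whole dataset (the efficiency frontier is simulation-wide, so
#' all DMUs are sampled together), compute the day-care/outpatient
#' construct scores and displaced interpretation ranges, interpret the
#' realization through the fuzzy engine, solve the two-phase VRS DEA
#' program for every DMU under each configured orientation, and append
#' the scores to the solution pool. The pool holds
#' `n_dmu * n_scenarios * n_sim` records per orientation.
#'
#' @param cfg a [pipeline_config()].
#' @param ds an `ecosystem_dataset`.
#' @param progress print scenario-level progress lines.
#' @return list with `pool` (an `rte_pool`) and `manifest` (config
#'   snapshot, record counts, wall-clock seconds, seed lineage).
#' @export
run_pipeline <- function(cfg, ds, progress = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"),
            inherits(ds, "ecosystem_dataset"))
  t0 <- proc.time()[["elapsed"]]
  for (sc in cfg$scenarios) validate_scenario(sc, ds)
  fuzzy <- cfg$fuzzy
  if (is.null(fuzzy)) fuzzy <- default_fuzzy_config(ds)
  use_fuzzy <- !isFALSE(fuzzy)
  plan <- build_plan(ds, uniform_cells = cfg$uniform_cells,
                     fixed_cells = cfg$fixed_cells,
                     weights = cfg$weights)
  n_dmu <- length(ds$dmu_names)
  n_sce <- length(cfg$scenarios)
  n_ori <- length(cfg$orientations)
  set.seed(cfg$seed)
  seed_mat <- matrix(sample.int(.Machine$integer.max,
                                cfg$n_sim * n_sce),
                     cfg$n_sim, n_sce)
  n_rec <- n_dmu * n_sce * cfg$n_sim * n_ori
  rec_dmu <- character(n_rec); rec_sce <- character(n_rec)
  rec_sim <- integer(n_rec); rec_ori <- character(n_rec)
  rec_rte <- numeric(n_rec); rec_slack <- numeric(n_rec)
  rec_class <- character(n_rec)
  pos <- 0L
  scen_ids <- vapply(cfg$scenarios, `[[`, character(1), "id")
  # per scenario: which variables need interpretation
  interp_vars <- if (use_fuzzy) names(fuzzy$interpretation) else character()
  ocode <- c(input = 0L, output = 1L)
  for (i in seq_len(n_sce)) {
    sc <- cfg$scenarios[[i]]
    sc_vars <- c(sc$input_vars, sc$output_vars)
    sc_interp <- intersect(interp_vars, sc_vars)
    for (j in seq_len(cfg$n_sim)) {
      set.seed(seed_mat[j, i])
      S <- sample_realization(plan)
      I <- if (use_fuzzy && length(sc_interp) > 0)
        interpret_dataset(S, fuzzy, variables = sc_interp) else S
      X <- I[, sc$input_vars, drop = FALSE]
      Y <- I[, sc$output_vars, drop = FALSE]
      X[X < cfg$input_floor] <- cfg$input_floor
      for (o in cfg$orientations) {
        r <- .dea_vrs_cpp(X, Y, ocode[[o]], seq_len(n_dmu))
        if (any(r$status != 0))
          stop("DEA solver failed at simulation ", j, ", scenario ",
               sc$id, ", DMU(s) ",
               paste(which(r$status != 0), collapse = ","))
        rte <- if (o == "input") r$objective else 1 / r$objective
        rte[abs(rte - 1) < 1e-6] <- 1
        idx <- pos + seq_len(n_dmu)
        rec_dmu[idx] <- ds$dmu_names
        rec_sce[idx] <- sc$id
        rec_sim[idx] <- j
        rec_ori[idx] <- o
        rec_rte[idx] <- rte
        rec_slack[idx] <- r$slack_total
        rec_class[idx] <- ifelse(abs(rte - 1) < 1e-6,
                                 ifelse(r$slack_total < 1e-6,
                                        "efficient", "weakly_efficient"),
                                 "inefficient")
        pos <- pos + n_dmu
      }
    }
    if (progress)
      message("scenario ", sc$id, " done (", i, "/", n_sce, ")")
  }
  # numerical guard: radial scores can overshoot 1 by solver tolerance
  rec_rte <- pmin(pmax(rec_rte, 0), 1)
  pool <- rte_pool(rec_dmu, rec_sce, rec_sim, rec_ori, rec_rte,
                   rec_slack, rec_class)
  manifest <- list(
    seed = cfg$seed, n_sim = cfg$n_sim, scenarios = scen_ids,
    orientations = cfg$orientations,
    n_dmu = n_dmu,
    weights = plan$weights,
    records_per_orientation = n_dmu * n_sce * cfg$n_sim,
    n_records = n_rec,
    elapsed_sec = proc.time()[["elapsed"]] - t0)
  list(pool = pool, manifest = manifest)
}

#' Run a full pre/post intervention study
#'
#' Runs the pipeline on the original dataset and on the edited dataset
#' (the randomization plan is rebuilt from the edited values), under
#' every configured orientation, then compares the pre and post pools
#' globally, per scenario and per DMU.
#'
#' @param cfg a [pipeline_config()].
#' @param ds an `ecosystem_dataset`.
#' @param spec an `intervention_spec`.
#' @param population optional named population vector for count-mode
#'   edits (see [apply_intervention()]).
#' @param progress print progress lines.
#' @return list with `pre`, `post` (pipeline results) and `reports`:
#'   per orientation, a `global` comparison plus named lists
#'   `by_scenario` and `by_dmu` of `comparison_report`s.
#' @export
run_intervention_study <- function(cfg, ds, spec, population = NULL,
                                   progress = FALSE) {
  ds_post <- apply_intervention(ds, spec, population = population)
  pre <- run_pipeline(cfg, ds, progress = progress)
  post <- run_pipeline(cfg, ds_post, progress = progress)
  reports <- lapply(setNames(nm = cfg$orientations), function(o) {
    p1 <- pre$pool[pre$pool$orientation == o, ]
    p2 <- post$pool[post$pool$orientation == o, ]
    cmp_subset <- function(col) {
      lv <- unique(p1[[col]])
      setNames(lapply(lv, function(v) {
        compare_pools(p1[p1[[col]] == v, ], p2[p2[[col]] == v, ],
                      params = cfg$stability)
      }), lv)
    }
    list(global = compare_pools(p1, p2, params = cfg$stability),
         by_scenario = cmp_subset("scenario"),
         by_dmu = cmp_subset("dmu"))
  })
  list(pre = pre, post = post, reports = reports)
}

#' Export an RTE pool to CSV
#'
#' @param pool an `rte_pool`.
#' @param path CSV file path.
#' @return `path`, invisibly. `read_pool()` reads it back.
#' @export
write_pool <- function(pool, path) {
  utils::write.csv(as.data.frame(pool), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pool
#' @export
read_pool <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_pool(df)
  structure(df, class = c("rte_pool", "data.frame"))
}
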