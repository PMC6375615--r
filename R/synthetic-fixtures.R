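#' Variable taxonomy template for synthetic datasets
#'
#' Returns the 57-variable descriptor table used by the synthetic
#' generator: 43 provision inputs (availability `T`, placement `P`,
#' workforce `Prof` across residential `R`, day `D` and outpatient `O`
#' care) and 14 utilisation outputs. The identifiers follow the
#' care-service naming taxonomy (service codes such as `R2`, `D1+D41`,
#' `O8+O10`); names not needed by the shipped scenario definitions are
#' synthetic fillers chosen in the same style.
#'
#' @return A descriptor `data.frame` with 57 rows.
#' @export
variable_template <- function() {
  inputs <- c(
    # availability
    "TR2", "TR4-R7", "TR8-R13", "TR12", "TR8+R11",
    "TD1", "TD41", "TD4other", "TD4other+D2-D3", "TO8+O10",
    # placement capacity
    "PR2", "PR4-R7", "PR2-R7", "PR7", "PR8+R11", "PR8-R13", "PR12",
    "PD1", "PD41", "PD1+D41", "PD4other", "PD4other+D2-D3", "PO8+O10",
    # workforce capacity
    "ProfTotR2", "ProfPsychiR2", "ProfPsychoDUER2", "ProfDUER4-R7",
    "ProfTotR4-R7", "ProfPsychiR4-R7", "ProfPsychoDUER4-R7",
    "ProfTotR2-R7", "ProfTotR8-R13", "ProfPsychoDUER8-R13",
    "ProfTotD1", "ProfTotD41", "ProfTotD1+D41", "ProfPsychiD1+D41",
    "ProfPsychoDUED1+D41", "ProfTotD4+D2-D3",
    "ProfTotO8+O10", "ProfPsychiO8+O10", "ProfPsychoO8+O10",
    "ProfDUEO8+O10")
  outputs <- c(
    "UDischargesR2", "UStayR2", "UReAdmissionR2",
    "UDischargesR4-R7", "UStayR4-R7", "UReAdmissionR4-R7",
    "UOccupR8-R13",
    "UD1", "UD41", "UD4other", "UD2-D3",
    "UPrevO8+O10", "UIncO8+O10", "UFrecO8+O10")
  parse_variable_descriptors(c(inputs, outputs))
}

#' Fixture generator configuration
#'
#' @param n_dmu number of DMUs (default 19).
#' @param template descriptor table (default [variable_template()]).
#' @param scales named list of log-normal scale parameters
#'   (`meanlog`, `sdlog`) per measure type; rates per 100,000
#'   inhabitants at magnitudes typical of regional mental-health
#'   systems (availability of order 1, placement of order 30,
#'   workforce of order 12, utilisation of order 300).
#' @param effect strength of the provision-to-utilisation link
#'   (utilisation outputs are proportional to
#'   `(0.25 + effect * provision index)` of their care group).
#' @param noise_sd log-scale noise of the utilisation outputs.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(n_dmu = 19, template = variable_template(),
                           scales = list(
                             T = list(meanlog = log(1.2), sdlog = 0.35),
                             P = list(meanlog = log(30), sdlog = 0.40),
                             Prof = list(meanlog = log(12), sdlog = 0.40),
                             U = list(meanlog = log(300), sdlog = 0.30)),
                           effect = 1.5, noise_sd = 0.15) {
  structure(list(n_dmu = n_dmu, template = template, scales = scales,
                 effect = effect, noise_sd = noise_sd),
            class = "fixture_config")
}

#' Generate a synthetic ecosystem dataset
#'
#' Provision (input) rates are drawn log-normally with measure-specific
#' scales; utilisation (output) rates are a monotone increasing function
#' of the mean provision level of the same care group plus log-normal
#' noise, so that efficiency frontiers are non-degenerate and outputs
#' correlate positively with their matched inputs. Deterministic given
#' the seed. The generator emulates the shape and positivity structure
#' of real small-area datasets, not any real magnitudes.
#'
#' @param cfg a [fixture_config()].
#' @param seed integer seed.
#' @return An `ecosystem_dataset` (`n_dmu` x 57 by default).
#' @export
generate_ecosystem <- function(cfg = fixture_config(), seed = 1) {
  stopifnot(inherits(cfg, "fixture_config"))
  set.seed(seed)
  tpl <- cfg$template
  n <- cfg$n_dmu
  dmu <- sprintf("SHA%02d", seq_len(n))
  vals <- matrix(0, n, nrow(tpl), dimnames = list(dmu, tpl$name))
  is_in <- tpl$role == "input"
  for (j in which(is_in)) {
    s <- cfg$scales[[tpl$measure[j]]]
    vals[, j] <- stats::rlnorm(n, s$meanlog, s$sdlog)
  }
  # per-DMU provision index per care group: mean of column-normalized inputs
  prov_index <- function(g) {
    cols <- which(is_in & tpl$care_group == g)
    z <- vals[, cols, drop = FALSE]
    z <- sweep(z, 2, colMeans(z), "/")
    rowMeans(z)
  }
  idx <- list(R = prov_index("R"), D = prov_index("D"), O = prov_index("O"))
  for (j in which(!is_in)) {
    g <- tpl$care_group[j]
    base <- idx[[g]] %||% rowMeans(do.call(cbind, idx))
    s <- cfg$scales[["U"]]
    lvl <- 0.25 + cfg$effect * base
    vals[, j] <- exp(s$meanlog) * lvl *
      stats::rlnorm(n, 0, cfg$noise_sd)
  }
  ecosystem_dataset(vals, tpl, dmu)
}

#' Generate a paired resource-reassignment intervention
#'
#' Builds `n_edits / 2` paired edits on workforce variables: each pair
#' decreases a source DMU and increases a target DMU by the same amount
#' on the same variable, so every affected column total is conserved
#' (a staff reassignment, not a hire). The amount is a fraction of the
#' source cell so the edit can never drive a value negative.
#'
#' @param ds an `ecosystem_dataset`.
#' @param n_edits even number of cell edits (= 2 x reassignments).
#' @param seed integer seed.
#' @param fraction fraction of the source cell moved (default 0.25).
#' @return An `intervention_spec`.
#' @export
generate_intervention <- function(ds, n_edits = 2, seed = 1,
                                  fraction = 0.25) {
  stopifnot(inherits(ds, "ecosystem_dataset"))
  if (n_edits %% 2 != 0) stop("n_edits must be even (paired edits)")
  if (n_edits == 0)
    return(intervention_spec("SYN-I0", "empty intervention",
                             data.frame()))
  set.seed(seed)
  wf <- ds$variables$name[ds$variables$measure == "Prof"]
  edits <- NULL
  for (p in seq_len(n_edits / 2)) {
    v <- sample(wf, 1)
    pos <- which(ds$values[, v] > 0)
    if (length(pos) < 2) stop("not enough positive cells in ", v)
    pair <- sample(pos, 2)
    amt <- fraction * ds$values[pair[1], v]
    edits <- rbind(edits, data.frame(
      dmu = ds$dmu_names[pair],
      variable = v,
      change = c(-amt, amt),
      mode = "rate",
      direction = c("decreasing", "increasing"),
      stringsAsFactors = FALSE))
  }
  intervention_spec(sprintf("SYN-I%d", n_edits / 2),
                    "synthetic paired workforce reassignment", edits)
}

#' Scenario set for the synthetic fixture
#'
#' The eleven shipped care-model scenarios plus, when `n > 11`,
#' synthetic filler scenarios (`SX1`, `SX2`, ...) built from the
#' remaining template variables, so that full-scale runs with the
#' reference scenario count (15) are possible on purely synthetic data.
#'
#' @param ds an `ecosystem_dataset` built on [variable_template()].
#' @param n total number of scenarios (default 15).
#' @return Named list of `scenario_spec`s.
#' @export
fixture_scenarios <- function(ds, n = 15) {
  base <- default_scenarios(ds)
  if (n <= length(base)) return(base[seq_len(n)])
  v <- ds$variables
  extra_in <- list(
    c("TR2", "PR2", "ProfTotR2"),
    c("TD1", "TD41", "PD1", "PD41"),
    c("TO8+O10", "PO8+O10", "ProfDUEO8+O10"),
    c("TR12", "PR12", "ProfTotR8-R13", "ProfPsychoDUER8-R13"))
  extra_out <- list(
    c("UDischargesR2", "UStayR2"),
    c("UD1", "UD41"),
    c("UPrevO8+O10", "UIncO8+O10"),
    c("UOccupR8-R13", "UReAdmissionR2"))
  need <- n - length(base)
  if (need > length(extra_in))
    stop("at most ", length(base) + length(extra_in),
         " fixture scenarios available")
  extra <- lapply(seq_len(need), function(i) {
    scenario_spec(paste0("SX", i), "synthetic filler scenario",
                  extra_in[[i]], extra_out[[i]], dataset = ds)
  })
  names(extra) <- vapply(extra, `[[`, character(1), "id")
  c(base, extra)
}

#' Synthesize an RTE pool matching target histogram frequencies
#'
#' Places `round(freq * n)` records at each interval: score-bin records
#' at the bin midpoint (class `inefficient`), penultimate-bin records
#' at score 1 with unit slack (`weakly_efficient`), last-bin records at
#' score 1 with zero slack (`efficient`). If the frequencies are not
#' exact multiples of `1/n` the nearest counts are used with a warning.
#' [bin_pool()] on the result recovers the requested frequencies
#' exactly whenever they are representable.
#'
#' @param freq vector of `inttot` relative frequencies summing to 1.
#' @param n pool size.
#' @param inttot total interval count (default 22).
#' @return An `rte_pool`.
#' @export
fig_style_pool <- function(freq, n, inttot = 22) {
  if (length(freq) != inttot) stop("freq must have length ", inttot)
  if (abs(sum(freq) - 1) > 1e-9) stop("frequencies must sum to 1")
  counts <- round(freq * n)
  if (any(abs(counts - freq * n) > 1e-9)) {
    warning("frequencies are not exact multiples of 1/n; ",
            "using nearest counts")
    # repair rounding drift on the largest bin
    counts[which.max(counts)] <- counts[which.max(counts)] + n - sum(counts)
  }
  nscore <- inttot - 2
  width <- 1 / nscore
  rte <- cls <- slack <- NULL
  for (h in seq_len(inttot)) {
    if (counts[h] == 0) next
    if (h <= nscore) {
      rte <- c(rte, rep((h - 0.5) * width, counts[h]))
      cls <- c(cls, rep("inefficient", counts[h]))
      slack <- c(slack, rep(0, counts[h]))
    } else if (h == inttot - 1) {
      rte <- c(rte, rep(1, counts[h]))
      cls <- c(cls, rep("weakly_efficient", counts[h]))
      slack <- c(slack, rep(1, counts[h]))
    } else {
      rte <- c(rte, rep(1, counts[h]))
      cls <- c(cls, rep("efficient", counts[h]))
      slack <- c(slack, rep(0, counts[h]))
    }
  }
  m <- length(rte)
  rte_pool(dmu = rep("synthetic", m), scenario = rep("synthetic", m),
           simulation = seq_len(m), orientation = rep("input", m),
           rte = rte, slack_total = slack, class = cls)
}

#' Write a complete fixture directory
#'
#' Dataset CSV, descriptor CSV, scenario YAML and an example
#' intervention YAML, all generated from code.
#'
#' @param dir output directory (created if needed).
#' @param cfg a [fixture_config()].
#' @param seed integer seed.
#' @return The directory path, invisibly.
#' @export
write_fixture <- function(dir, cfg = fixture_config(), seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- generate_ecosystem(cfg, seed = seed)
  write_dataset(ds, file.path(dir, "dataset.csv"))
  write_descriptors(ds$variables, file.path(dir, "descriptors.csv"))
  file.copy(system.file("extdata", "scenarios-care-model.yaml",
                        package = "rtesim", mustWork = TRUE),
            file.path(dir, "scenarios.yaml"), overwrite = TRUE)
  write_intervention(generate_intervention(ds, n_edits = 4, seed = seed),
                     file.path(dir, "intervention.yaml"))
  invisible(dir)
}
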