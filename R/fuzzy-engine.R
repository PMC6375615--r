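#' Fuzzy interpretation configuration
#'
#' The inference layer encodes an expert community-care model: day-care
#' (D) and outpatient (O) provision are summarized into construct scores
#' on a 0-100 scale, and the appropriateness range of each residential
#' (R) variable is displaced by "IF D/O ... THEN ..." rules before the
#' sampled values are re-expressed relative to that range.
#'
#' A configuration is a list with elements:
#' \describe{
#'   \item{constructs}{for each of `D` and `O`: `variables` (provision
#'     variable names feeding the construct) and `universe` (named list
#'     of `c(min, max)` expert ranges per variable).}
#'   \item{rules}{5x5 integer matrix; entry `[a, b]` is the consequent
#'     label index fired when D has label `a` and O has label `b`
#'     (1 = very little ... 5 = very much).}
#'   \item{interpretation}{named list per interpreted variable:
#'     `x_left`, `x_right` (base appropriateness range),
#'     `left_universe` (`c(min, max)` expert range over which the new
#'     left bound is defuzzified), `profile` (see
#'     [interpret_value()]) and `adjust` (logical; rule-based
#'     displacement on/off).}
#'   \item{score_universe}{construct output range, default `c(0, 100)`.}
#' }
#'
#' `default_fuzzy_config()` derives a ready-to-run configuration from a
#' dataset: D/O constructs are fed by the provision (availability,
#' placement, workforce) variables of their care group with universes
#' `[0, 1.25 max]`; residential-group input variables get a base range
#' of plus/minus 10\% around their median, a left universe of
#' `[0, max]`, the tent-shaped `"centre_distance"` profile and
#' rule-based adjustment. These data-driven ranges stand in for expert
#' elicitation and are meant to be replaced by a hand-written
#' configuration in real studies.
#'
#' @param ds an `ecosystem_dataset`.
#' @return A `fuzzy_config` list.
#' @export
default_fuzzy_config <- function(ds) {
  stopifnot(inherits(ds, "ecosystem_dataset"))
  v <- ds$variables
  prov <- v$role == "input"
  grp_vars <- function(g) v$name[prov & v$care_group == g]
  mk_universe <- function(vars) {
    u <- lapply(vars, function(nm) {
      mx <- max(ds$values[, nm])
      c(0, if (mx > 0) 1.25 * mx else 1)
    })
    names(u) <- vars
    u
  }
  d_vars <- grp_vars("D"); o_vars <- grp_vars("O")
  interp <- list()
  for (nm in grp_vars("R")) {
    col <- ds$values[, nm]
    med <- stats::median(col)
    mx <- max(col)
    interp[[nm]] <- list(x_left = 0.9 * med, x_right = 1.1 * med,
                         left_universe = c(0, if (mx > 0) mx else 1),
                         profile = "centre_distance", adjust = TRUE)
  }
  cfg <- list(constructs = list(D = list(variables = d_vars,
                                         universe = mk_universe(d_vars)),
                                O = list(variables = o_vars,
                                         universe = mk_universe(o_vars))),
              rules = default_rule_base(),
              interpretation = interp,
              score_universe = c(0, 100))
  class(cfg) <- "fuzzy_config"
  cfg
}

#' Default monotone rule base
#'
#' The shipped 5x5 table encodes the causal direction of the care
#' model: the scarcer the day and outpatient provision, the further the
#' residential appropriateness floor is displaced toward "much"/"very
#' much". Entry `[a, b]` = `6 - ceiling((a + b) / 2)`, so e.g. D
#' "little" with O "very little" fires "much".
#'
#' @return 5x5 integer matrix of consequent label indices.
#' @export
default_rule_base <- function() {
  outer(1:5, 1:5, function(a, b) 6L - as.integer(ceiling((a + b) / 2)))
}

validate_rule_base <- function(rules) {
  if (!is.matrix(rules) || !all(dim(rules) == c(5, 5)))
    stop("rule base must be a 5x5 matrix")
  if (!all(rules %in% 1:5))
    stop("rule consequents must be label indices 1..5")
  invisible(rules)
}

# normalized mean provision level in [0, 1] for one construct
construct_level <- function(values, spec) {
  if (length(spec$variables) == 0)
    return(rep(0, NROW(values)))
  vals <- values[, spec$variables, drop = FALSE]
  z <- vapply(spec$variables, function(nm) {
    u <- spec$universe[[nm]]
    pmin(pmax((vals[, nm] - u[1]) / (u[2] - u[1]), 0), 1)
  }, numeric(NROW(values)))
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  rowMeans(z)
}

#' Day-care and outpatient construct scores
#'
#' Summarizes the provision variables of each care group into a single
#' score on the construct scale (default 0-100; 0 = no availability of
#' the corresponding services, 100 = maximum availability). The
#' min-max-normalized group mean is fuzzified on the unit five-set
#' partition and projected onto the score scale by product-sum gravity
#' over symmetric output sets, which makes the score linear in the
#' group mean, bounded, and monotone non-decreasing in every
#' contributing variable.
#'
#' @param dmu_row named numeric vector (or 1-row matrix) of variable
#'   values for one DMU, or a full DMU x variable matrix.
#' @param config a `fuzzy_config`.
#' @return For a single row, `c(D = , O = )`; for a matrix, an
#'   `n x 2` matrix of scores.
#' @export
compute_constructs <- function(dmu_row, config) {
  one <- is.null(dim(dmu_row))
  values <- if (one) matrix(dmu_row, 1, dimnames = list(NULL, names(dmu_row)))
            else dmu_row
  for (cn in c("D", "O")) {
    miss <- setdiff(config$constructs[[cn]]$variables, colnames(values))
    if (length(miss) > 0)
      stop("construct ", cn, ": missing variable(s): ",
           paste(miss, collapse = ", "))
  }
  p01 <- fuzzy_partition(0, 1)
  pout <- fuzzy_partition(config$score_universe[1], config$score_universe[2],
                          extremes = "symmetric")
  sc <- vapply(c("D", "O"), function(cn) {
    z <- construct_level(values, config$constructs[[cn]])
    defuzzify(fuzzify(z, p01), pout)
  }, numeric(nrow(values)))
  if (is.null(dim(sc))) sc <- matrix(sc, 1, dimnames = list(NULL, c("D", "O")))
  colnames(sc) <- c("D", "O")
  if (one) c(D = unname(sc[1, 1]), O = unname(sc[1, 2])) else sc
}

# Fire the rule base on construct scores and return the normalized
# defuzzified left-bound position in [0, 1]; vectorized over rows of
# `scores` (n x 2 matrix, columns D and O).
rule_position <- function(scores, config) {
  validate_rule_base(config$rules)
  pscore <- fuzzy_partition(config$score_universe[1],
                            config$score_universe[2])
  muD <- fuzzify(scores[, "D"], pscore)
  muO <- fuzzify(scores[, "O"], pscore)
  n <- nrow(muD)
  M <- matrix(0, n, 5)
  for (a in 1:5) for (b in 1:5) {
    act <- muD[, a] * muO[, b]
    cns <- config$rules[a, b]
    M[, cns] <- M[, cns] + act
  }
  p01 <- fuzzy_partition(0, 1)
  defuzzify(M, p01)
}

#' Rule-based displacement of an interpretation range
#'
#' Fires the configured rule base on the fuzzified construct scores,
#' defuzzifies the aggregated consequent over the variable's expert
#' `left_universe` to obtain the new left bound, and shifts the right
#' bound so that the range width is preserved exactly:
#' `x_right' = x_left' + (x_right - x_left)`.
#'
#' @param base list with `x_left` and `x_right` (the static range).
#' @param scores construct scores, `c(D = , O = )`.
#' @param config a `fuzzy_config` (supplies the rule base).
#' @param left_universe `c(min, max)` range for the new left bound.
#' @return list with displaced `x_left` and `x_right`.
#' @export
adjust_range <- function(base, scores, config, left_universe) {
  if (base$x_left > base$x_right) stop("invalid base range")
  z <- rule_position(matrix(c(scores[["D"]], scores[["O"]]), 1,
                            dimnames = list(NULL, c("D", "O"))),
                     config)
  width <- base$x_right - base$x_left
  x_left <- left_universe[1] + z * (left_universe[2] - left_universe[1])
  list(x_left = x_left, x_right = x_left + width)
}

#' Piecewise-linear value interpretation
#'
#' Re-expresses a sampled value relative to its appropriateness range
#' `[x_left, x_right]`. Shipped profiles:
#' \describe{
#'   \item{`"identity"`}{no interpretation, `x_int = x`.}
#'   \item{`"centred_literal"`}{`x_int = (x_right - x_left) - x`: the
#'     range width minus the value, applied on the whole axis. Note it
#'     can be negative when values exceed the range width.}
#'   \item{`"centre_distance"`}{tent-shaped distance from the range
#'     centre, `x_int = |x - (x_left + x_right)/2|`: zero at the most
#'     appropriate (centred) value and growing linearly with deviation
#'     on either side, which suits input-oriented efficiency reading
#'     (less deviation = less "resource misfit" consumed).}
#' }
#' All profiles are piecewise linear and monotone within each linear
#' piece.
#'
#' @param x numeric vector of sampled values.
#' @param x_left,x_right range bounds (scalars or vectors like `x`).
#' @param profile profile name.
#' @return Interpreted values, same length as `x`.
#' @export
interpret_value <- function(x, x_left, x_right,
                            profile = c("identity", "centred_literal",
                                        "centre_distance")) {
  profile <- match.arg(profile)
  if (any(x_left > x_right)) stop("invalid range: x_left > x_right")
  switch(profile,
         identity = x,
         centred_literal = (x_right - x_left) - x,
         centre_distance = abs(x - (x_left + x_right) / 2))
}

#' Interpret a sampled dataset through the fuzzy engine
#'
#' For each configured variable, computes (or reuses) the construct
#' scores per DMU, displaces the interpretation ranges of the variables
#' flagged `adjust = TRUE`, and applies the variable's interpretation
#' profile. Variables without an interpretation entry pass through
#' unchanged. The result is deterministic given the sampled matrix.
#'
#' @param sampled DMU x variable numeric matrix (one Monte-Carlo
#'   realization, or the observed dataset).
#' @param config a `fuzzy_config`.
#' @param variables which variables to interpret (default: all
#'   configured ones present in the matrix).
#' @param scores optional precomputed construct score matrix
#'   (`n x 2`, columns `D`, `O`).
#' @return Matrix of the same shape as `sampled`.
#' @export
interpret_dataset <- function(sampled, config, variables = NULL,
                              scores = NULL) {
  todo <- intersect(names(config$interpretation), colnames(sampled))
  if (!is.null(variables)) todo <- intersect(todo, variables)
  if (length(todo) == 0) return(sampled)
  needs_adjust <- vapply(config$interpretation[todo],
                         function(e) isTRUE(e$adjust), logical(1))
  z <- NULL
  if (any(needs_adjust)) {
    if (is.null(scores)) scores <- compute_constructs(sampled, config)
    z <- rule_position(scores, config)
  }
  out <- sampled
  for (nm in todo) {
    e <- config$interpretation[[nm]]
    width <- e$x_right - e$x_left
    if (isTRUE(e$adjust)) {
      xl <- e$left_universe[1] + z * diff(e$left_universe)
      xr <- xl + width
    } else {
      xl <- e$x_left; xr <- e$x_right
    }
    out[, nm] <- interpret_value(sampled[, nm], xl, xr,
                                 profile = e$profile %||% "identity")
  }
  out
}

#' Read / write a fuzzy configuration as YAML
#'
#' @param config a `fuzzy_config`.
#' @param path YAML file path.
#' @return `read_fuzzy_config()` returns a `fuzzy_config`.
#' @export
write_fuzzy_config <- function(config, path) {
  ser <- list(constructs = config$constructs,
              rules = as.vector(t(config$rules)),
              interpretation = config$interpretation,
              score_universe = config$score_universe)
  yaml::write_yaml(ser, path, precision = 15)
  invisible(path)
}

#' @rdname write_fuzzy_config
#' @export
read_fuzzy_config <- function(path) {
  raw <- yaml::read_yaml(path)
  rules <- matrix(as.integer(raw$rules), 5, 5, byrow = TRUE)
  validate_rule_base(rules)
  interp <- lapply(raw$interpretation, function(e) {
    e$left_universe <- as.numeric(unlist(e$left_universe))
    e
  })
  cfg <- list(constructs = lapply(raw$constructs, function(cn) {
                list(variables = as.character(unlist(cn$variables)),
                     universe = lapply(cn$universe, function(u)
                       as.numeric(unlist(u))))
              }),
              rules = rules,
              interpretation = interp,
              score_universe = as.numeric(unlist(raw$score_universe)))
  class(cfg) <- "fuzzy_config"
  cfg
}
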