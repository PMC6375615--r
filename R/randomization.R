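#' Per-cell randomization distributions
#'
#' Each observed rate \eqn{x} is turned into a statistical distribution
#' expressing the structural uncertainty of the system. The default law
#' is triangular, \eqn{T[w_{tl} x,\ x,\ w_{tr} x]} with weights
#' \eqn{w_{tl} = 0.9} and \eqn{w_{tr} = 1.1}: the observed value is the
#' mode and the support a plus/minus 10\% relative band. Selected cells
#' may instead use a uniform law \eqn{U[x,\ w_{ur} x]} with
#' \eqn{w_{ur} = 1.1}. A zero observation has no relative band and stays
#' degenerate at 0, as does any cell when all weights equal 1.
#'
#' @param x observed non-negative value.
#' @param w_tl,w_tr triangular band weights, `0 < w_tl <= 1 <= w_tr`.
#' @param w_ur uniform upper weight, `>= 1`.
#' @return A `cell_distribution` object with fields `kind`
#'   (`"triangular"`, `"uniform"` or `"degenerate"`), `min`, `mode`
#'   (triangular only), `max` and `source_value`.
#' @examples
#' triangularize(0.4398)          # T[0.3958, 0.4398, 0.4838]
#' uniformize(439.12)             # U[439.12, 483.03]
#' @export
triangularize <- function(x, w_tl = 0.9, w_tr = 1.1) {
  if (x < 0) stop("observed value must be non-negative, got ", x)
  if (!(w_tl > 0 && w_tl <= 1 && w_tr >= 1))
    stop("need 0 < w_tl <= 1 <= w_tr")
  lo <- w_tl * x; hi <- w_tr * x
  kind <- if (hi - lo <= 0) "degenerate" else "triangular"
  structure(list(kind = kind, min = lo, mode = x, max = hi,
                 source_value = x),
            class = "cell_distribution")
}

#' @rdname triangularize
#' @export
uniformize <- function(x, w_ur = 1.1) {
  if (x < 0) stop("observed value must be non-negative, got ", x)
  if (w_ur < 1) stop("need w_ur >= 1")
  hi <- w_ur * x
  kind <- if (hi - x <= 0) "degenerate" else "uniform"
  structure(list(kind = kind, min = x, mode = NA_real_, max = hi,
                 source_value = x),
            class = "cell_distribution")
}

#' @export
print.cell_distribution <- function(x, ...) {
  cat(switch(x$kind,
             triangular = sprintf("T[%g, %g, %g]", x$min, x$mode, x$max),
             uniform    = sprintf("U[%g, %g]", x$min, x$max),
             degenerate = sprintf("degenerate at %g", x$min)), "\n")
  invisible(x)
}

#' Build a whole-dataset randomization plan
#'
#' Assigns a distribution to every cell of the dataset: cells listed in
#' `uniform_cells` get the uniform law of [uniformize()], all others the
#' triangular law of [triangularize()]. Cells listed in `fixed_cells`
#' (or with value 0) remain degenerate, i.e. are never randomized.
#'
#' Which cells are uniform or exempt is dataset-specific expert
#' configuration, not a rule; the default is none.
#'
#' @param ds an `ecosystem_dataset`.
#' @param uniform_cells `data.frame` with columns `dmu` and `variable`,
#'   or `NULL`.
#' @param fixed_cells same format; cells kept at their observed value.
#' @param weights named list/vector with `w_tl`, `w_tr`, `w_ur`.
#' @return A `randomization_plan`: matrices `kind` (0 degenerate,
#'   1 triangular, 2 uniform), `min`, `mode`, `max`, aligned with the
#'   dataset, plus the weights.
#' @export
build_plan <- function(ds, uniform_cells = NULL, fixed_cells = NULL,
                       weights = list(w_tl = 0.9, w_tr = 1.1, w_ur = 1.1)) {
  stopifnot(inherits(ds, "ecosystem_dataset"))
  w <- modifyList(list(w_tl = 0.9, w_tr = 1.1, w_ur = 1.1), as.list(weights))
  x <- ds$values
  kind <- matrix(1L, nrow(x), ncol(x), dimnames = dimnames(x))
  lo <- w$w_tl * x; mo <- x; hi <- w$w_tr * x
  cell_index <- function(cells, what) {
    if (is.null(cells) || NROW(cells) == 0) return(NULL)
    i <- match(cells$dmu, ds$dmu_names)
    j <- match(cells$variable, ds$variables$name)
    bad <- is.na(i) | is.na(j)
    if (any(bad))
      stop("unknown ", what, " cell reference: ",
           paste(cells$dmu[bad], cells$variable[bad],
                 sep = "/", collapse = ", "))
    cbind(i, j)
  }
  uc <- cell_index(uniform_cells, "uniform")
  if (!is.null(uc)) {
    kind[uc] <- 2L
    lo[uc] <- x[uc]; mo[uc] <- NA_real_; hi[uc] <- w$w_ur * x[uc]
  }
  fc <- cell_index(fixed_cells, "fixed")
  if (!is.null(fc)) {
    kind[fc] <- 0L
    lo[fc] <- x[fc]; mo[fc] <- x[fc]; hi[fc] <- x[fc]
  }
  zero_width <- (hi - lo) <= 0
  kind[zero_width] <- 0L
  lo[zero_width] <- x[zero_width]; hi[zero_width] <- x[zero_width]
  structure(list(kind = kind, min = lo, mode = mo, max = hi,
                 source = x, weights = w),
            class = "randomization_plan")
}

#' @export
print.randomization_plan <- function(x, ...) {
  cat("<randomization_plan> ", nrow(x$kind), "x", ncol(x$kind),
      " cells: ", sum(x$kind == 1L), " triangular, ",
      sum(x$kind == 2L), " uniform, ", sum(x$kind == 0L),
      " degenerate\n", sep = "")
  invisible(x)
}

#' Draw one randomized realization of the dataset
#'
#' Every cell is drawn independently from its plan distribution using
#' the current R random stream (seed it with `set.seed()` for
#' reproducibility). Triangular cells are sampled by inverse-CDF
#' transform of a single uniform draw, so a run is exactly reproducible
#' across platforms given the seed.
#'
#' @param plan a `randomization_plan`.
#' @return Numeric matrix with the plan's dimnames; every value lies in
#'   the closed support of its cell distribution.
#' @export
sample_realization <- function(plan) {
  stopifnot(inherits(plan, "randomization_plan"))
  k <- plan$kind
  u <- matrix(runif(length(k)), nrow(k), ncol(k))
  out <- plan$min  # degenerate default
  tri <- k == 1L
  if (any(tri)) {
    a <- plan$min[tri]; m <- plan$mode[tri]; b <- plan$max[tri]
    uu <- u[tri]
    fc <- (m - a) / (b - a)
    left <- uu < fc
    r <- numeric(length(uu))
    r[left] <- a[left] + sqrt(uu[left] * (b[left] - a[left]) * (m[left] - a[left]))
    r[!left] <- b[!left] -
      sqrt((1 - uu[!left]) * (b[!left] - a[!left]) * (b[!left] - m[!left]))
    out[tri] <- r
  }
  uni <- k == 2L
  if (any(uni))
    out[uni] <- plan$min[uni] + u[uni] * (plan$max[uni] - plan$min[uni])
  dimnames(out) <- dimnames(k)
  out
}

#' Serialize / restore a randomization plan configuration
#'
#' Only the configuration is stored (weights plus the uniform and fixed
#' cell lists), not the cell parameters, which are always rebuilt from
#' the dataset via the multiplicative band rules.
#'
#' @param plan a `randomization_plan`.
#' @param path YAML file path.
#' @return `write_plan_config()` returns `path` invisibly;
#'   `read_plan_config()` a list with `weights`, `uniform_cells`,
#'   `fixed_cells` suitable for [build_plan()].
#' @export
write_plan_config <- function(plan, path) {
  cells_df <- function(code) {
    idx <- which(plan$kind == code, arr.ind = TRUE)
    if (nrow(idx) == 0) return(list())
    apply(idx, 1, function(ij) {
      list(dmu = rownames(plan$kind)[ij[1]],
           variable = colnames(plan$kind)[ij[2]])
    })
  }
  yaml::write_yaml(list(weights = plan$weights,
                        uniform_cells = cells_df(2L),
                        fixed_cells = cells_df(0L)),
                   path, precision = 15)
  invisible(path)
}

#' @rdname write_plan_config
#' @export
read_plan_config <- function(path) {
  raw <- yaml::read_yaml(path)
  to_df <- function(x) {
    if (is.null(x) || length(x) == 0) return(NULL)
    data.frame(dmu = vapply(x, `[[`, character(1), "dmu"),
               variable = vapply(x, `[[`, character(1), "variable"),
               stringsAsFactors = FALSE)
  }
  list(weights = raw$weights,
       uniform_cells = to_df(raw$uniform_cells),
       fixed_cells = to_df(raw$fixed_cells))
}
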