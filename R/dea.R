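#' Variable-returns-to-scale DEA problems
#'
#' Bundles the input matrix `X` (n DMUs x m inputs), the output matrix
#' `Y` (n x s) and the orientation. Inputs must be strictly positive for
#' the envelopment program to be well-posed; zero or negative inputs
#' (possible after fuzzy interpretation) are floored at `input_floor`.
#'
#' @param X,Y numeric matrices with one row per DMU.
#' @param orientation `"input"` or `"output"`.
#' @param input_floor small positive floor applied to `X`.
#' @return A `dea_problem` object.
#' @export
dea_problem <- function(X, Y, orientation = c("input", "output"),
                        input_floor = 1e-9) {
  orientation <- match.arg(orientation)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  if (nrow(X) < 1 || ncol(X) < 1 || ncol(Y) < 1)
    stop("need at least one DMU, one input and one output")
  if (anyNA(X) || anyNA(Y)) stop("NA in DEA data")
  if (any(Y < 0)) stop("outputs must be non-negative")
  X[X < input_floor] <- input_floor
  structure(list(X = X, Y = Y, orientation = orientation),
            class = "dea_problem")
}

#' Solve the two-phase VRS envelopment program
#'
#' Phase 1 solves the radial envelopment LP under variable returns to
#' scale (convexity constraint on the peer weights): input orientation
#' minimizes the radial input contraction `theta`; output orientation
#' maximizes the radial output expansion `phi`. Phase 2 fixes the radial
#' factor and maximizes total slack, which is what distinguishes fully
#' efficient from weakly efficient frontier units. Both orientations
#' report the relative technical efficiency on a common `[0, 1]` scale:
#' `rte = theta` (input) or `rte = 1/phi` (output); the raw objective is
#' kept alongside.
#'
#' @param problem a [dea_problem()].
#' @param k DMU index to evaluate (`solve_all()` evaluates every DMU).
#' @param tol boundary tolerance for the efficiency classification.
#' @return `solve_vrs()` returns a `dea_result` list: `rte`,
#'   `raw_objective`, `lambdas`, `input_slacks`, `output_slacks`,
#'   `slack_total`, `efficiency_class`. `solve_all()` returns a list of
#'   them, index-aligned with the rows of `X`.
#' @export
solve_vrs <- function(problem, k, tol = 1e-6) {
  stopifnot(inherits(problem, "dea_problem"))
  n <- nrow(problem$X)
  if (k < 1 || k > n) stop("DMU index out of range")
  solve_all(problem, which = k, tol = tol)[[1]]
}

#' @rdname solve_vrs
#' @param which integer vector of DMU indices (default all).
#' @export
solve_all <- function(problem, which = NULL, tol = 1e-6) {
  stopifnot(inherits(problem, "dea_problem"))
  n <- nrow(problem$X)
  if (is.null(which)) which <- seq_len(n)
  ocode <- if (problem$orientation == "input") 0L else 1L
  r <- .dea_vrs_cpp(problem$X, problem$Y, ocode, as.integer(which))
  if (any(r$status != 0))
    stop("LP solver failed for DMU(s) ",
         paste(which[r$status != 0], collapse = ", "),
         " (status ", paste(unique(r$status[r$status != 0]), collapse = ","),
         "); orientation=", problem$orientation)
  lapply(seq_along(which), function(q) {
    obj <- r$objective[q]
    rte <- if (problem$orientation == "input") obj else 1 / obj
    res <- structure(list(rte = rte, raw_objective = obj,
                          lambdas = r$lambda[q, ],
                          input_slacks = r$input_slacks[q, ],
                          output_slacks = r$output_slacks[q, ],
                          slack_total = r$slack_total[q],
                          dmu = which[q]),
                     class = "dea_result")
    res$efficiency_class <- classify(res, tol = tol)
    res
  })
}

#' Efficiency classification
#'
#' A DMU is `efficient` when its score is 1 and total slack is zero
#' (both within `tol`), `weakly_efficient` when the score is 1 but
#' residual slacks remain, and `inefficient` otherwise.
#'
#' @param result a `dea_result` from [solve_vrs()].
#' @param tol boundary tolerance.
#' @return `"efficient"`, `"weakly_efficient"` or `"inefficient"`.
#' @export
classify <- function(result, tol = 1e-6) {
  if (abs(result$rte - 1) < tol) {
    if (result$slack_total < tol) "efficient" else "weakly_efficient"
  } else "inefficient"
}

#' @export
print.dea_result <- function(x, ...) {
  cat(sprintf("<dea_result> DMU %d: rte = %.4f (%s), total slack = %.4g\n",
              x$dmu, x$rte, x$efficiency_class, x$slack_total))
  invisible(x)
}
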