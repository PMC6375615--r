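#' Five-set fuzzy partitions
#'
#' Every linguistic variable in the inference layer is described by five
#' normal fuzzy sets labelled *very little*, *little*, *standard*,
#' *much* and *very much*. The two extreme sets are linear shoulders
#' (membership 1 at the universe bound) and the three interior sets are
#' triangles spanning peak to peak. With evenly spaced peaks this
#' geometry guarantees, by construction, that memberships always sum to
#' one and that at most two sets are active at any point.
#'
#' `extremes = "symmetric"` instead treats all five sets as symmetric
#' equal-area triangles centred on their peaks, so that centre-of-gravity
#' defuzzification interpolates the peaks exactly and reaches the
#' universe bounds; this variant is used for the 0-100 construct output
#' scale.
#'
#' @param min,max universe bounds, `min < max`.
#' @param peaks optional 5 strictly increasing peak abscissae
#'   (default evenly spaced over the universe).
#' @param extremes `"shoulder"` (default) or `"symmetric"`.
#' @return A `fuzzy_partition` with peaks, set areas and set centroids.
#' @export
fuzzy_partition <- function(min, max, peaks = NULL,
                            extremes = c("shoulder", "symmetric")) {
  extremes <- match.arg(extremes)
  if (!(max > min)) stop("degenerate universe: need max > min")
  if (is.null(peaks)) peaks <- seq(min, max, length.out = 5)
  peaks <- as.numeric(peaks)
  if (length(peaks) != 5 || any(diff(peaks) <= 0))
    stop("peaks must be 5 strictly increasing abscissae")
  if (peaks[1] < min || peaks[5] > max)
    stop("peaks must lie inside the universe")
  if (extremes == "shoulder") {
    areas <- centroids <- numeric(5)
    # left shoulder: flat on [min, p1], linear down to 0 at p2
    a_flat <- peaks[1] - min
    a_tri <- (peaks[2] - peaks[1]) / 2
    areas[1] <- a_flat + a_tri
    centroids[1] <- (a_flat * (min + peaks[1]) / 2 +
                     a_tri * (peaks[1] + (peaks[2] - peaks[1]) / 3)) / areas[1]
    for (i in 2:4) {
      areas[i] <- (peaks[i + 1] - peaks[i - 1]) / 2
      centroids[i] <- (peaks[i - 1] + peaks[i] + peaks[i + 1]) / 3
    }
    a_flat <- max - peaks[5]
    a_tri <- (peaks[5] - peaks[4]) / 2
    areas[5] <- a_flat + a_tri
    centroids[5] <- (a_flat * (peaks[5] + max) / 2 +
                     a_tri * (peaks[5] - (peaks[5] - peaks[4]) / 3)) / areas[5]
  } else {
    areas <- rep(1, 5)
    centroids <- peaks
  }
  structure(list(universe = c(min, max), peaks = peaks,
                 areas = areas, centroids = centroids,
                 labels = c("very little", "little", "standard",
                            "much", "very much"),
                 extremes = extremes),
            class = "fuzzy_partition")
}

#' Fuzzification: crisp value to membership degrees
#'
#' Values are clamped to the universe; the result has at most two
#' nonzero degrees and they sum to one.
#'
#' @param x numeric vector of crisp values.
#' @param p a [fuzzy_partition()].
#' @return `length(x)` x 5 membership matrix.
#' @export
fuzzify <- function(x, p) {
  stopifnot(inherits(p, "fuzzy_partition"))
  x <- pmin(pmax(x, p$universe[1]), p$universe[2])
  m <- matrix(0, length(x), 5)
  pk <- p$peaks
  below <- x <= pk[1]
  above <- x >= pk[5]
  m[below, 1] <- 1
  m[above, 5] <- 1
  mid <- !below & !above
  if (any(mid)) {
    xi <- x[mid]
    seg <- findInterval(xi, pk, rightmost.closed = TRUE)  # 1..4
    w <- (xi - pk[seg]) / (pk[seg + 1] - pk[seg])
    rows <- which(mid)
    m[cbind(rows, seg)] <- 1 - w
    m[cbind(rows, seg + 1)] <- m[cbind(rows, seg + 1)] + w
  }
  m
}

#' Defuzzification by the product-sum gravity method
#'
#' Centre of gravity of the membership-scaled sets:
#' \eqn{\sum_k m_k c_k A_k / \sum_k m_k A_k}, where \eqn{c_k} and
#' \eqn{A_k} are each set's centroid and area (product inference, sum
#' aggregation).
#'
#' @param m membership vector of length 5, or a matrix with 5 columns
#'   (one row per case).
#' @param p a [fuzzy_partition()].
#' @return Crisp value(s) inside the universe.
#' @export
defuzzify <- function(m, p) {
  stopifnot(inherits(p, "fuzzy_partition"))
  if (is.null(dim(m))) m <- matrix(m, 1)
  if (ncol(m) != 5) stop("membership must have 5 degrees")
  denom <- as.numeric(m %*% p$areas)
  if (any(denom <= 0))
    stop("defuzzification undefined: all memberships are zero")
  as.numeric(m %*% (p$centroids * p$areas)) / denom
}
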