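# Entropy-weight method (EWM) and TOPSIS ranking.
#
# Pipeline: min-max standardize with benefit/cost directions -> column
# proportions -> information entropy -> weights -> ideal solutions ->
# weighted distances -> closeness -> rank.

#' Min-max standardization with direction handling
#'
#' Benefit columns map to (x - min) / (max - min), cost columns to
#' (max - x) / (max - min), so that for every indicator 1 is best and 0 is
#' worst and every non-constant column attains both.
#'
#' @param table An \code{\link{indicator_table}}.
#' @param constant Policy for constant columns: \code{"error"} (default)
#'   aborts naming the column; \code{"drop"} removes it with a warning (it
#'   carries no information, so it would receive zero entropy weight anyway).
#' @return A matrix of class \code{standardized_matrix} with values in
#'   [0, 1], carrying the directions used as an attribute.
#' @export
standardize_minmax <- function(table, constant = c("error", "drop")) {
  constant <- match.arg(constant)
  stopifnot(inherits(table, "indicator_table"))
  x <- unclass(table)
  rng <- apply(x, 2, range)
  flat <- rng[1, ] == rng[2, ]
  if (any(flat)) {
    if (constant == "error")
      stop("constant indicator column(s): ",
           paste(colnames(x)[flat], collapse = ", "))
    warning("dropping constant indicator column(s): ",
            paste(colnames(x)[flat], collapse = ", "))
    x <- x[, !flat, drop = FALSE]
    rng <- rng[, !flat, drop = FALSE]
    if (ncol(x) == 0L)
      stop("all indicator columns are constant")
  }
  dirs <- attr(table, "directions")[colnames(x)]
  z <- sweep(sweep(x, 2, rng[1, ]), 2, rng[2, ] - rng[1, ], "/")
  cost <- dirs == "cost"
  z[, cost] <- 1 - z[, cost, drop = FALSE]
  structure(z, class = c("standardized_matrix", "matrix", "array"),
            directions = dirs, year = attr(table, "year"))
}

#' Column proportions of a standardized matrix
#'
#' Each standardized column is rescaled to sum to one, giving the
#' per-object share P_ij used by the entropy computation.
#'
#' @param z A \code{standardized_matrix}.
#' @return Matrix of the same shape with unit column sums.
#' @export
column_proportions <- function(z) {
  cs <- colSums(z)
  if (any(cs == 0))
    stop("column(s) sum to zero; cannot form proportions: ",
         paste(colnames(z)[cs == 0], collapse = ", "))
  sweep(unclass(z), 2, cs, "/")
}

#' Information entropy of a proportion column
#'
#' e = -(1/ln m) sum_i P_i ln P_i, with the convention 0 ln 0 = 0 (min-max
#' standardization produces exact zeros, so the convention is load-bearing).
#' Uniform proportions give e = 1 (no information), a one-hot column e = 0.
#'
#' @param p Proportion vector: non-negative, summing to 1 (tolerance 1e-9).
#' @param m Number of objects; defaults to \code{length(p)}.
#' @return Entropy in [0, 1].
#' @export
entropy_value <- function(p, m = length(p)) {
  if (any(p < 0)) stop("proportions must be non-negative")
  if (abs(sum(p) - 1) > 1e-9) stop("proportions must sum to 1")
  if (m < 2L) stop("need at least 2 objects")
  p <- p[p > 0]
  -sum(p * log(p)) / log(m)
}

#' Entropy weights from column entropies
#'
#' Information utility d_j = 1 - e_j, weight w_j = d_j / sum(d). Indicators
#' whose values spread the objects apart (low entropy) get high weight.
#'
#' @param e Named numeric vector of column entropies in [0, 1].
#' @return An object of class \code{ewm_weights}: data frame with columns
#'   \code{indicator}, \code{entropy}, \code{utility}, \code{weight}
#'   (weights sum to 1).
#' @export
entropy_weights <- function(e) {
  if (any(e < 0 | e > 1)) stop("entropies must lie in [0, 1]")
  d <- 1 - e
  if (sum(d) == 0)
    stop("no discriminating indicator: all entropies equal 1")
  w <- d / sum(d)
  structure(data.frame(indicator = if (is.null(names(e)))
                         paste0("ind", seq_along(e)) else names(e),
                       entropy = unname(e), utility = unname(d),
                       weight = unname(w), row.names = NULL),
            class = c("ewm_weights", "data.frame"))
}

#' @export
print.ewm_weights <- function(x, ...) {
  cat("Entropy-method indicator weights\n")
  out <- data.frame(indicator = x$indicator,
                    e = sprintf("%.3f", x$entropy),
                    d = sprintf("%.3f", x$utility),
                    weight = sprintf("%.2f%%", 100 * x$weight))
  print(out, row.names = FALSE)
  invisible(x)
}

#' Positive and negative ideal solutions
#'
#' Column-wise maxima (positive ideal) and minima (negative ideal) of the
#' standardized matrix. With min-max standardization and no constant
#' columns these are the all-ones and all-zeros vectors.
#'
#' @param z A \code{standardized_matrix}.
#' @return List with vectors \code{positive} and \code{negative}.
#' @export
ideal_solutions <- function(z) {
  list(positive = apply(z, 2, max), negative = apply(z, 2, min))
}

#' Distances to the ideal solutions
#'
#' Two weighting conventions are offered. The default,
#' \code{"weights-linear"}, puts the weights linearly inside the squared
#' deviations, \eqn{d_i^\pm = \sqrt{\sum_j w_j (z_{ij} - z_j^\pm)^2}}; this
#' is the convention under which the published 2022 distance table is
#' reproduced, and it bounds d in [0, 1] since the weights sum to 1 and z
#' lies in [0, 1]. The \code{"literal"} variant forms the weighted matrix
#' v_ij = w_j z_ij first and takes plain Euclidean distances to its column
#' extrema (weights effectively squared inside the metric).
#'
#' @param z A \code{standardized_matrix}.
#' @param weights An \code{\link{ewm_weights}} object (or numeric vector)
#'   aligned with the columns of \code{z}.
#' @param ideals Optional list as from \code{\link{ideal_solutions}};
#'   computed from \code{z} when omitted.
#' @param variant \code{"weights-linear"} (default) or \code{"literal"}.
#' @return List with vectors \code{d_plus} and \code{d_minus}.
#' @export
topsis_distances <- function(z, weights, ideals = NULL,
                             variant = c("weights-linear", "literal")) {
  variant <- match.arg(variant)
  w <- if (inherits(weights, "ewm_weights")) {
    stats::setNames(weights$weight, weights$indicator)[colnames(z)]
  } else weights
  if (length(w) != ncol(z) || anyNA(w))
    stop("weights do not align with the matrix columns")
  if (is.null(ideals)) ideals <- ideal_solutions(z)
  zp <- ideals$positive
  zn <- ideals$negative
  zm <- unclass(z)
  if (variant == "weights-linear") {
    d_plus <- sqrt(colSums(w * (t(zm) - zp)^2))
    d_minus <- sqrt(colSums(w * (t(zm) - zn)^2))
  } else {
    v <- sweep(zm, 2, w, "*")
    vp <- zp * w
    vn <- zn * w
    d_plus <- sqrt(colSums((t(v) - vp)^2))
    d_minus <- sqrt(colSums((t(v) - vn)^2))
  }
  list(d_plus = unname(d_plus), d_minus = unname(d_minus))
}

#' Relative closeness to the ideal solution
#'
#' T_i = d_i^- / (d_i^- + d_i^+), in [0, 1]; 1 means the object coincides
#' with the positive ideal.
#'
#' @param d_plus,d_minus Non-negative distance vectors.
#' @return Closeness vector.
#' @export
closeness <- function(d_plus, d_minus) {
  if (any(d_plus < 0) || any(d_minus < 0))
    stop("distances must be non-negative")
  both0 <- d_plus == 0 & d_minus == 0
  if (any(both0))
    stop("degenerate object(s) with zero distance to both ideals")
  d_minus / (d_minus + d_plus)
}

#' Ranks from closeness scores
#'
#' Rank 1 is the highest closeness; ties are broken by input order, so the
#' result is always a permutation of 1..m.
#'
#' @param tc Closeness vector.
#' @return Integer rank vector.
#' @export
rank_closeness <- function(tc) {
  ord <- order(-tc)
  rk <- integer(length(tc))
  rk[ord] <- seq_along(tc)
  rk
}

#' Entropy-weighted TOPSIS evaluation
#'
#' Runs the full chain on a screened indicator table: min-max
#' standardization with the table's direction tags, column proportions,
#' information entropy, entropy weights, ideal solutions, weighted
#' distances, closeness and ranks.
#'
#' @inheritParams standardize_minmax
#' @inheritParams topsis_distances
#' @return An object of class \code{ewm_topsis}: list with
#'   \describe{
#'     \item{\code{weights}}{an \code{\link{ewm_weights}} data frame,}
#'     \item{\code{result}}{a \code{topsis_result} data frame with columns
#'       \code{object}, \code{d_plus}, \code{d_minus}, \code{closeness},
#'       \code{rank} in input object order,}
#'     \item{\code{standardized}}{the standardized matrix,}
#'     \item{\code{ideals}}{the ideal-solution vectors,}
#'     \item{\code{variant}, \code{year}}{bookkeeping.}
#'   }
#' @examples
#' tab <- trial_indicator_table(2022)
#' ev <- ewm_topsis(tab)
#' ev$result[ev$result$rank == 1, ]
#' @export
ewm_topsis <- function(table, variant = c("weights-linear", "literal"),
                       constant = c("error", "drop")) {
  variant <- match.arg(variant)
  z <- standardize_minmax(table, constant = constant)
  P <- column_proportions(z)
  e <- apply(P, 2, entropy_value, m = nrow(P))
  w <- entropy_weights(e)
  ideals <- ideal_solutions(z)
  d <- topsis_distances(z, w, ideals, variant = variant)
  tc <- closeness(d$d_plus, d$d_minus)
  result <- structure(
    data.frame(object = rownames(z), d_plus = d$d_plus,
               d_minus = d$d_minus, closeness = tc,
               rank = rank_closeness(tc), row.names = NULL),
    class = c("topsis_result", "data.frame"))
  structure(list(weights = w, result = result, standardized = z,
                 ideals = ideals, variant = variant,
                 year = attr(table, "year")),
            class = "ewm_topsis")
}

#' @export
print.ewm_topsis <- function(x, ...) {
  yr <- if (is.null(x$year)) "" else paste0(" (", x$year, ")")
  cat(sprintf("EWM-TOPSIS evaluation%s, variant '%s'\n\n", yr, x$variant))
  print(x$weights)
  cat("\n")
  out <- x$result
  out$d_plus <- sprintf("%.3f", out$d_plus)
  out$d_minus <- sprintf("%.3f", out$d_minus)
  out$closeness <- sprintf("%.3f", out$closeness)
  print(out, row.names = FALSE)
  invisible(x)
}
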