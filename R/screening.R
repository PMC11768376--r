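# Indicator screening: Pearson correlation among candidate indicators and
# pruning of redundant ones before the multi-criteria evaluation.

#' Pairwise Pearson correlations among indicators
#'
#' Computes the Pearson correlation matrix over the objects of an indicator
#' table, with two-sided p-values from the usual t transform
#' t = r sqrt((m-2)/(1-r^2)) on m - 2 degrees of freedom.
#'
#' @param table An \code{\link{indicator_table}} with at least 3 objects and
#'   no constant column.
#' @return An object of class \code{correlation_report}: list with matrices
#'   \code{r} and \code{p}, and (until \code{\link{prune_indicators}} is
#'   applied) empty \code{retained}/\code{dropped} slots.
#' @export
pearson_matrix <- function(table) {
  stopifnot(inherits(table, "indicator_table"))
  m <- nrow(table)
  if (m < 3L)
    stop("need at least 3 objects for correlation screening")
  sds <- apply(table, 2, stats::sd)
  if (any(sds == 0))
    stop("constant indicator column(s): ",
         paste(colnames(table)[sds == 0], collapse = ", "))
  r <- stats::cor(unclass(table))
  tt <- r * sqrt((m - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), df = m - 2, lower.tail = FALSE)
  diag(p) <- 0
  p[abs(r) >= 1 - 1e-12] <- 0
  diag(p) <- NA_real_
  structure(list(r = r, p = p, retained = character(),
                 dropped = data.frame(indicator = character(),
                                      because_of = character(),
                                      r = numeric())),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, digits = 2, ...) {
  cat("Pearson correlation report over", ncol(x$r), "indicators\n")
  print(round(x$r, digits))
  if (length(x$retained)) {
    cat("Retained:", paste(x$retained, collapse = ", "), "\n")
    if (nrow(x$dropped))
      cat("Dropped:",
          paste(sprintf("%s (|r|=%.2f with %s)", x$dropped$indicator,
                        abs(x$dropped$r), x$dropped$because_of),
                collapse = "; "), "\n")
  }
  invisible(x)
}

#' Prune redundant indicators by correlation threshold
#'
#' Greedy scan in priority order: each indicator is retained unless its
#' absolute correlation with an already-retained indicator reaches the
#' threshold, in which case it is dropped and the retained partner that
#' triggered the drop is recorded. Deterministic given the priority order.
#'
#' @param report A \code{correlation_report} from \code{\link{pearson_matrix}}.
#' @param threshold Absolute-correlation cutoff in (0, 1]; values above 1
#'   disable pruning.
#' @param keep_priority Character vector ordering all indicators from most to
#'   least preferred; defaults to the column order of the report.
#' @return The report with \code{retained} and \code{dropped} filled in.
#' @export
prune_indicators <- function(report, threshold = 0.8,
                             keep_priority = colnames(report$r)) {
  stopifnot(inherits(report, "correlation_report"))
  if (threshold <= 0)
    stop("threshold must be positive")
  all_ind <- colnames(report$r)
  if (!setequal(keep_priority, all_ind))
    stop("keep_priority must cover exactly the report's indicators")
  retained <- character()
  dropped <- data.frame(indicator = character(), because_of = character(),
                        r = numeric())
  for (ind in keep_priority) {
    if (length(retained)) {
      rr <- report$r[ind, retained]
      hit <- which(abs(rr) >= threshold)
      if (length(hit)) {
        k <- hit[which.max(abs(rr[hit]))]
        dropped <- rbind(dropped,
                         data.frame(indicator = ind,
                                    because_of = retained[k],
                                    r = unname(rr[k])))
        next
      }
    }
    retained <- c(retained, ind)
  }
  report$retained <- retained
  report$dropped <- dropped
  report
}

#' Screen the indicators of a decision matrix
#'
#' Two modes. \code{"paper"} (default) keeps an explicit retained list --
#' by default \{ET, Y, WUE, NPFP, TSS, VC\}, the set kept in the published
#' trial evaluation after its correlation analysis. \code{"auto"} applies
#' the greedy threshold rule of \code{\link{prune_indicators}} to the
#' table's own correlations.
#'
#' @param table An \code{\link{indicator_table}} of candidate indicators.
#' @param mode \code{"paper"} or \code{"auto"}.
#' @param retained Retained list for paper mode; indicators absent from the
#'   table are ignored with a warning.
#' @param threshold,keep_priority Passed to \code{\link{prune_indicators}}
#'   in auto mode.
#' @return List with the screened \code{table} (columns subset, directions
#'   carried over) and the \code{report} (\code{NULL} in paper mode).
#' @export
screen_indicators <- function(table, mode = c("paper", "auto"),
                              retained = c("ET", "Y", "WUE", "NPFP",
                                           "TSS", "VC"),
                              threshold = 0.8,
                              keep_priority = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "indicator_table"))
  if (mode == "paper") {
    missing <- setdiff(retained, colnames(table))
    if (length(missing)) {
      warning("retained indicator(s) not in table: ",
              paste(missing, collapse = ", "))
      retained <- intersect(retained, colnames(table))
    }
    keep <- retained
    report <- NULL
  } else {
    report <- pearson_matrix(table)
    if (is.null(keep_priority))
      keep_priority <- colnames(table)
    report <- prune_indicators(report, threshold, keep_priority)
    keep <- report$retained
    # restore the table's own column order
    keep <- intersect(colnames(table), keep)
  }
  dirs <- attr(table, "directions")[keep]
  list(table = indicator_table(unclass(table)[, keep, drop = FALSE],
                               dirs, year = attr(table, "year")),
       report = report)
}
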