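#' @keywords internal
"_PACKAGE"

# Treatment order of the trial design: nitrogen level varies slowest in the
# printed tables (W1N1, W2N1, W3N1, ..., W3N3), CK last.
.treatment_order <- c("W1N1", "W2N1", "W3N1",
                      "W1N2", "W2N2", "W3N2",
                      "W1N3", "W2N3", "W3N3", "CK")

#' Load a packaged trial table
#'
#' The package ships the published per-treatment tables of a two-season
#' (2022/2023) deficit-irrigation by nitrogen eggplant trial as plain CSV
#' fixtures: seasonal water consumption and yield (\code{"table1"}), fruit
#' nutritional quality (\code{"table2"}), the experimental design with
#' nitrogen rates and seasonal irrigation totals (\code{"table6"}), and the
#' growth-stage calendar (\code{"table7"}).
#'
#' @param name One of \code{"table1"}, \code{"table2"}, \code{"table6"},
#'   \code{"table7"}.
#' @return A data frame; treatment rows follow the design order
#'   W1N1, W2N1, W3N1, W1N2, ..., W3N3, CK within each year.
#' @examples
#' head(wn_fixture("table1"))
#' @export
wn_fixture <- function(name = c("table1", "table2", "table6", "table7")) {
  name <- match.arg(name)
  file <- switch(name,
    table1 = "table1_et_yield.csv",
    table2 = "table2_quality.csv",
    table6 = "table6_design.csv",
    table7 = "table7_stages.csv")
  path <- system.file("extdata", file, package = "wntopsis", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Construct an indicator table
#'
#' An indicator table is the decision matrix of a multi-criteria evaluation:
#' one row per evaluated object (treatment), one column per indicator, plus a
#' direction tag per indicator saying whether larger values are preferable
#' (\code{"benefit"}) or smaller ones (\code{"cost"}).
#'
#' @param values Numeric matrix with row names (object ids) and column names
#'   (indicator ids). At least 2 rows and 1 column; no missing values.
#' @param directions Named character vector mapping every indicator to
#'   \code{"benefit"} or \code{"cost"}. A single unnamed value is recycled.
#' @param year Optional label for the season the table belongs to.
#' @return An object of class \code{indicator_table}: the matrix with
#'   \code{directions} and \code{year} attributes.
#' @export
indicator_table <- function(values, directions, year = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("indicator values must be numeric")
  if (nrow(values) < 2L)
    stop("an indicator table needs at least 2 objects (rows)")
  if (ncol(values) < 1L)
    stop("an indicator table needs at least 1 indicator (column)")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("obj", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    stop("indicator columns must be named")
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at object '%s', indicator '%s'",
                 rownames(values)[idx[1L]], colnames(values)[idx[2L]]))
  }
  if (length(directions) == 1L && is.null(names(directions)))
    directions <- stats::setNames(rep(directions, ncol(values)),
                                  colnames(values))
  if (!all(colnames(values) %in% names(directions))) {
    miss <- setdiff(colnames(values), names(directions))
    stop("no direction given for indicator(s): ", paste(miss, collapse = ", "))
  }
  directions <- directions[colnames(values)]
  if (!all(directions %in% c("benefit", "cost")))
    stop("directions must be 'benefit' or 'cost'")
  structure(values, class = c("indicator_table", "matrix", "array"),
            directions = directions, year = year)
}

#' @export
print.indicator_table <- function(x, ...) {
  yr <- attr(x, "year")
  cat(sprintf("Indicator table: %d objects x %d indicators%s\n",
              nrow(x), ncol(x),
              if (is.null(yr)) "" else paste0(" (", yr, ")")))
  dirs <- attr(x, "directions")
  cat("Directions:", paste(sprintf("%s=%s", names(dirs),
                                   substr(dirs, 1, 1)), collapse = " "), "\n")
  print(unclass(structure(x, directions = NULL, year = NULL)), ...)
  invisible(x)
}

#' Read an indicator table from CSV
#'
#' Expects a header row, object ids in the first column and numeric indicator
#' columns after it. Column order is preserved.
#'
#' @param path CSV file path.
#' @inheritParams indicator_table
#' @return An \code{\link{indicator_table}}.
#' @export
read_indicator_table <- function(path, directions, year = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L)
    stop("expected an object-id column plus at least one indicator column")
  ids <- df[[1L]]
  vals <- df[-1L]
  for (j in seq_along(vals)) {
    cell <- trimws(vals[[j]])
    blank <- !nzchar(cell)
    if (any(blank))
      stop(sprintf("missing value at object '%s', indicator '%s'",
                   ids[which(blank)[1L]], names(vals)[j]))
    num <- suppressWarnings(as.numeric(cell))
    if (anyNA(num))
      stop(sprintf("non-numeric value '%s' at object '%s', indicator '%s'",
                   cell[which(is.na(num))[1L]],
                   ids[which(is.na(num))[1L]], names(vals)[j]))
    vals[[j]] <- num
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  indicator_table(m, directions, year = year)
}

#' Write an indicator table to CSV
#'
#' Inverse of \code{\link{read_indicator_table}}; values are written at full
#' precision so a write-then-read round trip is lossless.
#'
#' @param table An \code{indicator_table}.
#' @param path Output CSV path.
#' @export
write_indicator_table <- function(table, path) {
  stopifnot(inherits(table, "indicator_table"))
  df <- data.frame(object = rownames(table), unclass(table),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a TOPSIS result table to CSV
#'
#' @param result A \code{topsis_result} (see \code{\link{ewm_topsis}}).
#' @param path Output CSV path.
#' @return The path, invisibly. Columns: \code{object}, \code{d_plus},
#'   \code{d_minus}, \code{closeness}, \code{rank}, in input object order.
#' @export
write_result_table <- function(result, path) {
  if (is.null(result) || NROW(result) == 0L)
    stop("empty result; nothing to write")
  stopifnot(inherits(result, "topsis_result"))
  utils::write.csv(as.data.frame(result), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Assemble the per-year trial indicator table
#'
#' Builds the decision matrix for one season from the packaged fixtures:
#' water consumption (ET) and yield (Y) from the seasonal table, fruit
#' quality from the quality table, and the derived efficiency indices
#' WUE = Y/ET, IWUE = Y/I and NPFP = 1000 Y / N-rate from the design table.
#' The zero-nitrogen control CK is excluded (NPFP is undefined there), so the
#' matrix has the nine fertilized treatments as rows.
#'
#' @param year Season, 2022 or 2023.
#' @param screened If \code{TRUE} (default) return the six retained
#'   indicators \{ET, Y, WUE, NPFP, TSS, VC\}; otherwise the nine measured
#'   candidates \{ET, Y, WUE, IWUE, NPFP, SP, SSC, TSS, VC\}.
#' @param directions Direction tags passed to \code{\link{indicator_table}}.
#'   The default \code{"benefit"} standardizes every indicator, ET included,
#'   in the benefit direction, which is the convention under which the
#'   published 2022 weights and distances are reproduced.
#' @return An \code{\link{indicator_table}} with 9 rows.
#' @examples
#' trial_indicator_table(2022)
#' @export
trial_indicator_table <- function(year, screened = TRUE,
                                  directions = "benefit") {
  if (!year %in% c(2022, 2023))
    stop("unknown fixture year: ", year, " (packaged years: 2022, 2023)")
  t1 <- wn_fixture("table1")
  t2 <- wn_fixture("table2")
  t6 <- wn_fixture("table6")
  t1 <- t1[t1$year == year & t1$treatment != "CK", ]
  t2 <- t2[t2$year == year & t2$treatment != "CK", ]
  t6 <- t6[t6$treatment != "CK", ]
  ord <- .treatment_order[.treatment_order != "CK"]
  t1 <- t1[match(ord, t1$treatment), ]
  t2 <- t2[match(ord, t2$treatment), ]
  t6 <- t6[match(ord, t6$treatment), ]
  irr <- t6[[sprintf("irrigation_%d_mm", year)]]
  m <- cbind(
    ET   = t1$et_mm,
    Y    = t1$yield_t_ha,
    WUE  = wue(t1$yield_t_ha, t1$et_mm),
    IWUE = iwue(t1$yield_t_ha, irr),
    NPFP = npfp(t1$yield_t_ha, t6$n_rate_kg_ha),
    SP   = t2$sp_mg_g,
    SSC  = t2$ssc_pct,
    TSS  = t2$tss_pct,
    VC   = t2$vc_mg_kg)
  rownames(m) <- ord
  if (screened)
    m <- m[, c("ET", "Y", "WUE", "NPFP", "TSS", "VC")]
  indicator_table(m, directions, year = year)
}
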