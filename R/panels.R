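#' Composition panel: year-by-category percentage shares
#'
#' A composition panel holds, for one workforce attribute (e.g. age band,
#' years of work experience, educational qualification, professional and
#' technical qualification), the percentage share of each category in each
#' calendar year. Every row describes a complete composition, so shares are
#' non-negative and sum to 100 up to a tolerance that absorbs published
#' rounding.
#'
#' @param shares numeric matrix, years as rows and categories as columns,
#'   in percent (0--100). Column names are the category labels.
#' @param years integer vector of calendar years, one per row of `shares`.
#'   Must be strictly increasing with no gaps.
#' @param attribute name of the attribute the panel describes.
#' @param tolerance maximum absolute deviation of a row sum from 100, in
#'   percentage points. Default 0.5 (published shares are typically rounded
#'   to one decimal place, so exact sums cannot be required).
#'
#' @return an object of class `composition_panel`: a list with elements
#'   `attribute`, `years`, `categories`, `shares` and `tolerance`.
#' @export
composition_panel <- function(shares, years, attribute = "attribute",
                              tolerance = 0.5) {
  shares <- as.matrix(shares)
  storage.mode(shares) <- "double"
  years <- as.integer(years)
  if (is.null(colnames(shares))) {
    colnames(shares) <- paste0("category_", seq_len(ncol(shares)))
  }
  rownames(shares) <- years
  panel <- structure(
    list(attribute = as.character(attribute),
         years = years,
         categories = colnames(shares),
         shares = shares,
         tolerance = as.numeric(tolerance)),
    class = "composition_panel"
  )
  validate_composition_panel(panel)
  panel
}

#' @export
print.composition_panel <- function(x, ...) {
  cat(sprintf("Composition panel: %s\n", x$attribute))
  cat(sprintf("  %d years (%d-%d), %d categories\n",
              length(x$years), min(x$years), max(x$years),
              length(x$categories)))
  print(round(x$shares, 2))
  invisible(x)
}

validate_composition_panel <- function(panel) {
  shares <- panel$shares
  years <- panel$years
  if (length(years) != nrow(shares)) {
    stop("number of years must match number of share rows", call. = FALSE)
  }
  if (anyNA(shares)) {
    bad <- which(is.na(shares), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric or missing share for year %d, category '%s'",
                 years[bad[1]], colnames(shares)[bad[2]]), call. = FALSE)
  }
  if (anyNA(years)) stop("missing year value", call. = FALSE)
  if (length(years) > 1 && any(diff(years) != 1L)) {
    stop("non-consecutive years: panel years must increase by one with no gaps",
         call. = FALSE)
  }
  if (any(shares < 0)) {
    bad <- which(shares < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative share for year %d, category '%s'",
                 years[bad[1]], colnames(shares)[bad[2]]), call. = FALSE)
  }
  sums <- rowSums(shares)
  off <- abs(sums - 100) > panel$tolerance
  if (any(off)) {
    i <- which(off)[1]
    stop(sprintf(
      "row sum %.2f for year %d outside 100 ± %.2f",
      sums[i], years[i], panel$tolerance), call. = FALSE)
  }
  invisible(panel)
}

#' Factor panel: reference series plus comparison series
#'
#' A factor panel pairs one reference series (the resource being explained,
#' e.g. the annual count of oral-health personnel) with `m >= 1` comparison
#' series (candidate drivers such as population, per-capita GDP, per-capita
#' health expenditure) observed over the same years. All series must be
#' strictly positive: initial-value normalization divides by the first
#' observation, and the series are levels (counts, percentages, RMB amounts)
#' for which zero or negative values are not meaningful.
#'
#' @param years integer vector of calendar years.
#' @param reference numeric vector, strictly positive, same length as `years`.
#' @param comparisons numeric matrix with one row per comparison series and
#'   one column per year (m x n). Row names are the factor names.
#' @param reference_name name of the reference series.
#'
#' @return an object of class `factor_panel`.
#' @export
factor_panel <- function(years, reference, comparisons,
                         reference_name = "reference") {
  comparisons <- as.matrix(comparisons)
  storage.mode(comparisons) <- "double"
  years <- as.integer(years)
  reference <- as.numeric(reference)
  if (is.null(rownames(comparisons))) {
    rownames(comparisons) <- paste0("factor_", seq_len(nrow(comparisons)))
  }
  colnames(comparisons) <- years
  panel <- structure(
    list(years = years,
         reference_name = as.character(reference_name),
         reference = reference,
         comparison_names = rownames(comparisons),
         comparisons = comparisons),
    class = "factor_panel"
  )
  validate_factor_panel(panel)
  panel
}

#' @export
print.factor_panel <- function(x, ...) {
  cat(sprintf("Factor panel: reference '%s', %d comparison series, %d years (%d-%d)\n",
              x$reference_name, nrow(x$comparisons), length(x$years),
              min(x$years), max(x$years)))
  cat("  comparisons:", paste(x$comparison_names, collapse = ", "), "\n")
  invisible(x)
}

validate_factor_panel <- function(panel) {
  n <- length(panel$years)
  if (length(panel$reference) != n || ncol(panel$comparisons) != n) {
    stop("all series must cover the same years", call. = FALSE)
  }
  if (nrow(panel$comparisons) < 1) {
    stop("a factor panel needs at least one comparison series", call. = FALSE)
  }
  if (anyNA(panel$reference) || anyNA(panel$comparisons)) {
    stop("missing value in factor panel", call. = FALSE)
  }
  if (any(panel$reference <= 0)) {
    k <- which(panel$reference <= 0)[1]
    stop(sprintf("series '%s' is not strictly positive at year %d",
                 panel$reference_name, panel$years[k]), call. = FALSE)
  }
  bad <- which(panel$comparisons <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("series '%s' is not strictly positive at year %d",
                 rownames(panel$comparisons)[bad[1, 1]],
                 panel$years[bad[1, 2]]), call. = FALSE)
  }
  invisible(panel)
}

#' Table dialect for reading and writing panels and result tables
#'
#' @param sep field delimiter (default comma).
#' @param value_digits decimal places for signed change values (default 3).
#' @param percent_digits decimal places for percentages and coefficients
#'   (default 2 for percentages; relational results use 3).
#' @return an object of class `table_dialect`.
#' @export
table_dialect <- function(sep = ",", value_digits = 3L, percent_digits = 2L) {
  stopifnot(value_digits >= 0, percent_digits >= 0)
  structure(list(sep = sep,
                 value_digits = as.integer(value_digits),
                 percent_digits = as.integer(percent_digits)),
            class = "table_dialect")
}

#' Round half away from zero
#'
#' Display rounding for result tables. R's `round()` rounds half to even;
#' published tables use the conventional half-up rule, so exact halves
#' (e.g. 36.765 -> 36.77) must move away from zero.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}
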