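#' Structural change values of a composition panel
#'
#' For each consecutive pair of years, the structural change value (SCV) of
#' a category is the end-of-period share minus the beginning-of-period
#' share, expressed as a signed fraction: an SCV of 0.018 means the
#' category's share rose by 1.8 percentage points over the period. Because
#' each year's shares sum to 100, each period's SCVs sum to (approximately)
#' zero.
#'
#' @param panel a [composition_panel()] with at least two years, or one year
#'   plus an explicit `baseline`.
#' @param baseline optional share vector (percent, same categories) for the
#'   year immediately preceding the panel; when supplied, an extra first
#'   period (baseline -> first panel year) is prepended. Published tables
#'   sometimes report a change for the panel's first year against an
#'   earlier, unpublished composition; the baseline argument makes that
#'   convention explicit rather than guessing one.
#' @return matrix of signed fractions, one row per period, rownames the
#'   period end years.
#' @export
structural_change_values <- function(panel, baseline = NULL) {
  shares <- panel$shares
  if (!is.null(baseline)) {
    baseline <- as.numeric(baseline)
    if (length(baseline) != ncol(shares)) {
      stop("baseline must have one share per category", call. = FALSE)
    }
    shares <- rbind(baseline, shares)
    rownames(shares) <- c(panel$years[1] - 1L, panel$years)
  }
  if (nrow(shares) < 2) {
    stop("no period to difference: need at least two years or a baseline",
         call. = FALSE)
  }
  scv <- diff(shares) / 100
  dimnames(scv) <- list(rownames(shares)[-1], panel$categories)
  scv
}

#' Structural change degree of one period
#'
#' The structural change degree (SCD) is 100 times the sum of the absolute
#' structural change values across categories: the total percentage-point
#' movement of the composition over the period, regardless of direction.
#'
#' @param scv_row numeric vector of signed fractions for one period.
#' @return the degree in percent (non-negative scalar).
#' @export
structural_change_degree <- function(scv_row) {
  100 * sum(abs(scv_row))
}

#' Structural change contribution rates of one period
#'
#' Each category's contribution rate (SCC) is its absolute structural change
#' value as a percentage of the period's structural change degree — the
#' share of the total movement that the category accounts for. When the
#' period shows no change at all (all SCVs zero) the rates are returned as
#' zeros and the result is flagged degenerate instead of producing 0/0.
#'
#' @param scv_row numeric vector of signed fractions for one period.
#' @return vector of percentages summing to 100 (or all zeros, with
#'   attribute `degenerate = TRUE`, for a no-change period).
#' @export
contribution_rates <- function(scv_row) {
  total <- sum(abs(scv_row))
  if (total == 0) {
    out <- rep(0, length(scv_row))
    names(out) <- names(scv_row)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- 100 * abs(scv_row) / total
  attr(out, "degenerate") <- FALSE
  out
}

#' Classify the trend of one category across periods
#'
#' A category trends positive when its share is gaining overall: the column
#' sum of its SCVs is positive and more than `majority` of the nonzero
#' period values are positive. The symmetric rule gives a negative trend;
#' anything else is mixed. A category whose SCVs are all zero is reported
#' as "no change".
#'
#' @param scv_column numeric vector of one category's SCVs over periods.
#' @param majority fraction of nonzero entries that must share the sign of
#'   the column sum (strictly exceeded); default 0.5.
#' @return one of `"positive"`, `"negative"`, `"mixed"`, `"no change"`.
#' @export
classify_trend <- function(scv_column, majority = 0.5) {
  nz <- scv_column[scv_column != 0]
  if (length(nz) == 0) return("no change")
  s <- sum(scv_column)
  if (s > 0 && mean(nz > 0) > majority) return("positive")
  if (s < 0 && mean(nz < 0) > majority) return("negative")
  "mixed"
}

#' Full structural change analysis of a composition panel
#'
#' Runs the three structural-change operations over every period of the
#' panel and assembles the standard result table: SCV matrix, SCD vector,
#' SCC matrix, degenerate-period flags and per-category trend labels.
#' All values are kept at full precision; rounding is applied only by
#' [write_result_table()].
#'
#' @inheritParams structural_change_values
#' @param scd_threshold optional SCD threshold (percent) above which a
#'   period is labelled "active" in the result; `NULL` (default) applies no
#'   label — no standard cutoff exists and the choice is the analyst's.
#' @return an object of class `structural_change_table`.
#' @export
run_structural_change <- function(panel, baseline = NULL,
                                  scd_threshold = NULL) {
  scv <- structural_change_values(panel, baseline)
  scd <- apply(scv, 1, structural_change_degree)
  scc_list <- apply(scv, 1, contribution_rates, simplify = FALSE)
  scc <- do.call(rbind, lapply(scc_list, as.numeric))
  dimnames(scc) <- dimnames(scv)
  degenerate <- vapply(scc_list, function(x) isTRUE(attr(x, "degenerate")),
                       logical(1))
  trend <- vapply(seq_len(ncol(scv)),
                  function(j) classify_trend(scv[, j]), character(1))
  names(trend) <- colnames(scv)
  end_years <- as.integer(rownames(scv))
  out <- structure(
    list(attribute = panel$attribute,
         periods = data.frame(start = end_years - 1L, end = end_years),
         scv = scv, scd = scd, scc = scc,
         degenerate = degenerate, trend = trend),
    class = "structural_change_table"
  )
  if (!is.null(scd_threshold)) {
    out$active <- scd > scd_threshold
  }
  out
}

#' @export
print.structural_change_table <- function(x, ...) {
  cat(sprintf("Structural change analysis: %s\n", x$attribute))
  df <- data.frame(year = x$periods$end,
                   round_half_up(x$scv, 3),
                   `SCD%` = round_half_up(x$scd, 2),
                   check.names = FALSE)
  print(df, row.names = FALSE)
  cat("Contribution rates (%):\n")
  print(round_half_up(x$scc, 2))
  cat("Trends:", paste(sprintf("%s=%s", names(x$trend), x$trend),
                       collapse = ", "), "\n")
  invisible(x)
}
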