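#' Configuration for grey relational analysis
#'
#' @param rho discrimination (resolution) coefficient in (0, 1]. Controls
#'   the contrast between coefficients: smaller values spread them out.
#'   Default 0.5, the conventional choice.
#' @param normalization dimensionless preprocessing of every series before
#'   comparison: `"initial_value"` (divide by the first observation, the
#'   default and the standard choice for growth-like level series),
#'   `"mean_value"` (divide by the series mean), or `"none"`.
#' @return an object of class `grey_config`.
#' @export
grey_config <- function(rho = 0.5,
                        normalization = c("initial_value", "mean_value", "none")) {
  normalization <- match.arg(normalization)
  if (!is.numeric(rho) || length(rho) != 1 || rho <= 0 || rho > 1) {
    stop("rho must be a single number in (0, 1]", call. = FALSE)
  }
  structure(list(rho = rho, normalization = normalization,
                 degree_aggregation = "mean"),
            class = "grey_config")
}

#' Initial-value normalization
#'
#' Divides a strictly positive series by its first observation, so every
#' series starts at 1 and only its growth shape remains. Multiplying a
#' series by any positive constant leaves the result unchanged.
#'
#' @param series strictly positive numeric vector.
#' @return normalized vector with first element 1.
#' @export
normalize_initial_value <- function(series) {
  if (any(series <= 0)) {
    stop("initial-value normalization requires a strictly positive series",
         call. = FALSE)
  }
  series / series[1]
}

#' Mean-value normalization
#'
#' Divides a strictly positive series by its arithmetic mean.
#'
#' @param series strictly positive numeric vector.
#' @return normalized vector with mean 1.
#' @export
normalize_mean_value <- function(series) {
  if (any(series <= 0)) {
    stop("mean-value normalization requires a strictly positive series",
         call. = FALSE)
  }
  series / mean(series)
}

normalize_series <- function(series, method) {
  switch(method,
         initial_value = normalize_initial_value(series),
         mean_value = normalize_mean_value(series),
         none = series)
}

#' Absolute difference matrix between reference and comparison series
#'
#' Computes the pointwise absolute differences between the normalized
#' reference series and each normalized comparison series, together with
#' the two-level (global) extrema over all series and all time points that
#' the Deng coefficient needs.
#'
#' @param ref_norm normalized reference vector (length n).
#' @param comp_norms m x n matrix of normalized comparison series.
#' @return list with `delta` (m x n matrix), `global_min`, `global_max`.
#' @export
delta_matrix <- function(ref_norm, comp_norms) {
  comp_norms <- rbind(comp_norms)
  if (length(ref_norm) != ncol(comp_norms)) {
    stop("reference and comparison series must have the same length",
         call. = FALSE)
  }
  delta <- abs(sweep(comp_norms, 2, ref_norm))
  list(delta = delta, global_min = min(delta), global_max = max(delta))
}

#' Grey relational coefficients (Deng form)
#'
#' The coefficient at series i, time k is
#' \deqn{\xi_i(k) = \frac{\Delta_{min} + \rho\,\Delta_{max}}
#'                      {\Delta_i(k) + \rho\,\Delta_{max}}}
#' with the min and max taken globally over all series and times. Values
#' lie in (0, 1]; a point whose difference attains the global minimum
#' scores 1. In the degenerate case where every comparison series is
#' identical to the reference (global max 0), all coefficients are 1.
#'
#' @param delta m x n matrix of absolute normalized differences.
#' @param global_min,global_max two-level extrema of `delta`.
#' @param rho discrimination coefficient in (0, 1].
#' @return m x n matrix of coefficients in (0, 1].
#' @export
grey_coefficients <- function(delta, global_min, global_max, rho = 0.5) {
  stopifnot(global_max >= global_min, global_min >= 0, rho > 0, rho <= 1)
  if (global_max == 0) {
    out <- delta
    out[] <- 1
    return(out)
  }
  (global_min + rho * global_max) / (delta + rho * global_max)
}

#' Relational degree of one comparison series
#'
#' The unweighted arithmetic mean of a series' grey relational coefficients
#' over time: its overall similarity score against the reference.
#'
#' @param coefficient_row numeric vector of coefficients for one series.
#' @return scalar in (0, 1].
#' @export
relational_degree <- function(coefficient_row) {
  if (length(coefficient_row) == 0) {
    stop("cannot take the degree of an empty coefficient row", call. = FALSE)
  }
  mean(coefficient_row)
}

#' Rank factors by relational degree
#'
#' Rank 1 goes to the largest degree. Ties get dense ranks — tied degrees
#' share the smaller rank and the next distinct degree takes the next
#' integer — and tied groups are reported in the `ties` attribute.
#'
#' @param degrees numeric vector of relational degrees (optionally named).
#' @return integer vector of ranks, a permutation of 1..m when there are no
#'   ties; attribute `ties` lists tied values (empty if none).
#' @export
rank_factors <- function(degrees) {
  if (length(degrees) == 0) stop("no degrees to rank", call. = FALSE)
  lev <- sort(unique(degrees), decreasing = TRUE)
  ranks <- match(degrees, lev)
  names(ranks) <- names(degrees)
  dup <- unique(degrees[duplicated(degrees)])
  attr(ranks, "ties") <- dup
  ranks
}

#' Full grey relational analysis of a factor panel
#'
#' Runs the complete Deng-style pipeline: normalization of the reference
#' and every comparison series, the absolute-difference matrix with its
#' global extrema, the coefficient matrix at the configured discrimination
#' coefficient, the per-factor relational degrees (mean over years), and
#' the descending rank of the factors.
#'
#' @param panel a [factor_panel()].
#' @param config a [grey_config()].
#' @return an object of class `grey_result` with elements `years`,
#'   `factor_names`, `config`, `normalized_reference`,
#'   `normalized_comparisons`, `delta`, `global_min`, `global_max`,
#'   `coefficients`, `degrees`, `ranks`.
#' @export
run_gra <- function(panel, config = grey_config()) {
  ref_norm <- normalize_series(panel$reference, config$normalization)
  comp_norms <- t(apply(panel$comparisons, 1, normalize_series,
                        method = config$normalization))
  dimnames(comp_norms) <- dimnames(panel$comparisons)
  dm <- delta_matrix(ref_norm, comp_norms)
  xi <- grey_coefficients(dm$delta, dm$global_min, dm$global_max, config$rho)
  degrees <- apply(xi, 1, relational_degree)
  structure(
    list(years = panel$years,
         factor_names = panel$comparison_names,
         config = config,
         normalized_reference = ref_norm,
         normalized_comparisons = comp_norms,
         delta = dm$delta,
         global_min = dm$global_min,
         global_max = dm$global_max,
         coefficients = xi,
         degrees = degrees,
         ranks = rank_factors(degrees)),
    class = "grey_result"
  )
}

#' @export
print.grey_result <- function(x, ...) {
  cat(sprintf(
    "Grey relational analysis: %d factors, %d years (%d-%d), rho = %g, %s normalization\n",
    length(x$factor_names), length(x$years), min(x$years), max(x$years),
    x$config$rho, x$config$normalization))
  df <- data.frame(factor = x$factor_names,
                   degree = round_half_up(x$degrees, 3),
                   rank = as.integer(x$ranks))
  print(df[order(df$rank), ], row.names = FALSE)
  if (length(attr(x$ranks, "ties")) > 0) {
    cat("Tied degrees:", paste(round_half_up(attr(x$ranks, "ties"), 3),
                               collapse = ", "), "\n")
  }
  invisible(x)
}
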