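#' Read a composition panel from a delimited or XLSX file
#'
#' The expected layout has one header row naming the categories, a first
#' column of calendar years, and one percentage share per cell. XLSX sheets
#' with the same layout are read through readxl when that package is
#' installed. The reader validates and never silently renormalizes: a row
#' whose shares do not sum to 100 within the tolerance is an error naming
#' the offending year.
#'
#' @param path file path (.csv/.tsv/.txt or .xlsx).
#' @param dialect a [table_dialect()]; its `sep` is used for delimited files.
#' @param attribute attribute name recorded on the panel; defaults to the
#'   file name without extension.
#' @param tolerance row-sum tolerance in percentage points (default 0.5).
#' @param sheet sheet name or index for XLSX input.
#' @return a validated [composition_panel()].
#' @export
read_composition_panel <- function(path, dialect = table_dialect(),
                                   attribute = NULL, tolerance = 0.5,
                                   sheet = 1) {
  df <- read_panel_table(path, dialect, sheet)
  if (is.null(attribute)) {
    attribute <- sub("\\.[A-Za-z]+$", "", basename(path))
  }
  years <- parse_year_column(df[[1]], path)
  mat <- parse_numeric_block(df[-1], years, path)
  ord <- order(years)
  composition_panel(mat[ord, , drop = FALSE], years[ord],
                    attribute = attribute, tolerance = tolerance)
}

#' Read a factor panel from a delimited or XLSX file
#'
#' Layout: first column is the year, remaining columns are series. The
#' reference series is the first data column unless named via `reference`;
#' column order is otherwise irrelevant.
#'
#' @inheritParams read_composition_panel
#' @param reference name of the reference column; default first data column.
#' @return a validated [factor_panel()].
#' @export
read_factor_panel <- function(path, dialect = table_dialect(),
                              reference = NULL, sheet = 1) {
  df <- read_panel_table(path, dialect, sheet)
  years <- parse_year_column(df[[1]], path)
  mat <- parse_numeric_block(df[-1], years, path)
  ord <- order(years)
  mat <- mat[ord, , drop = FALSE]
  years <- years[ord]
  if (is.null(reference)) reference <- colnames(mat)[1]
  if (!reference %in% colnames(mat)) {
    stop(sprintf("reference series '%s' not found in %s", reference, path),
         call. = FALSE)
  }
  comp <- t(mat[, setdiff(colnames(mat), reference), drop = FALSE])
  factor_panel(years, mat[, reference], comp, reference_name = reference)
}

read_panel_table <- function(path, dialect, sheet = 1) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading XLSX requires the readxl package", call. = FALSE)
    }
    df <- as.data.frame(readxl::read_excel(path, sheet = sheet),
                        check.names = FALSE)
  } else {
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else dialect$sep
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
  }
  if (ncol(df) < 2) stop(sprintf("%s: need a year column plus data columns", path),
                         call. = FALSE)
  df
}

parse_year_column <- function(x, path) {
  years <- suppressWarnings(as.integer(x))
  if (anyNA(years)) {
    stop(sprintf("%s: missing or non-integer year in row %d",
                 path, which(is.na(years))[1]), call. = FALSE)
  }
  years
}

parse_numeric_block <- function(df, years, path) {
  mat <- sapply(df, function(col) suppressWarnings(as.numeric(col)))
  mat <- matrix(mat, nrow = length(years),
                dimnames = list(years, names(df)))
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop(sprintf("%s: non-numeric cell at year %d, column '%s'",
                 path, years[bad[1]], colnames(mat)[bad[2]]), call. = FALSE)
  }
  mat
}

#' Write a composition panel in the canonical delimited layout
#'
#' @param panel a [composition_panel()].
#' @param path output file path.
#' @param dialect a [table_dialect()].
#' @export
write_composition_panel <- function(panel, path, dialect = table_dialect()) {
  df <- data.frame(year = panel$years, check.names = FALSE)
  df[panel$categories] <- panel$shares
  utils::write.table(df, path, sep = dialect$sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a factor panel in the canonical delimited layout
#'
#' The reference series is the first data column.
#'
#' @param panel a [factor_panel()].
#' @inheritParams write_composition_panel
#' @export
write_factor_panel <- function(panel, path, dialect = table_dialect()) {
  df <- data.frame(year = panel$years, check.names = FALSE)
  df[[panel$reference_name]] <- panel$reference
  df[panel$comparison_names] <- t(panel$comparisons)
  utils::write.table(df, path, sep = dialect$sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a result table
#'
#' Serializes a [run_structural_change()] or [run_gra()] result to a
#' delimited file (or a markdown table) in the conventional published
#' layout: structural-change tables carry one row per period with the
#' signed change values, the degree (%) and the contribution rates (%);
#' relational tables carry one coefficient row per year followed by a
#' "Relational degree" row and a "Rank by relational degree" row. Display
#' rounding (half-up, to the dialect's decimal places) happens here and
#' only here.
#'
#' @param result a `structural_change_table` or `grey_result`.
#' @param path output file path.
#' @param dialect a [table_dialect()].
#' @param format `"csv"` (delimited, per dialect) or `"markdown"`.
#' @export
write_result_table <- function(result, path, dialect = table_dialect(),
                               format = c("csv", "markdown")) {
  UseMethod("write_result_table")
}

#' @export
write_result_table.structural_change_table <- function(result, path,
                                                       dialect = table_dialect(),
                                                       format = c("csv", "markdown")) {
  format <- match.arg(format)
  if (length(result$periods$end) == 0) {
    stop("empty result: no periods to write", call. = FALSE)
  }
  vd <- dialect$value_digits
  pd <- dialect$percent_digits
  df <- data.frame(year = result$periods$end, check.names = FALSE)
  df[paste0("scv_", colnames(result$scv))] <-
    format_fixed(round_half_up(result$scv, vd), vd)
  df[["scd_percent"]] <- format_fixed(round_half_up(result$scd, pd), pd)
  df[paste0("scc_", colnames(result$scc))] <-
    format_fixed(round_half_up(result$scc, pd), pd)
  emit_table(df, path, dialect, format)
}

#' @export
write_result_table.grey_result <- function(result, path,
                                           dialect = table_dialect(),
                                           format = c("csv", "markdown")) {
  format <- match.arg(format)
  if (length(result$degrees) == 0 || length(result$years) == 0) {
    stop("empty result: nothing to write", call. = FALSE)
  }
  d <- 3L  # relational coefficients and degrees print to 3 d.p.
  coef <- t(result$coefficients)  # years as rows
  df <- data.frame(year = as.character(result$years), check.names = FALSE)
  df[result$factor_names] <- apply(coef, 2, function(col)
    format_fixed(round_half_up(col, d), d))
  deg <- c("Relational degree",
           format_fixed(round_half_up(result$degrees, d), d))
  rnk <- c("Rank by relational degree", as.character(result$ranks))
  out <- rbind(df,
               stats::setNames(as.data.frame(as.list(deg)), names(df)),
               stats::setNames(as.data.frame(as.list(rnk)), names(df)))
  emit_table(out, path, dialect, format)
}

format_fixed <- function(x, digits) {
  formatC(x, format = "f", digits = digits)
}

emit_table <- function(df, path, dialect, format) {
  if (format == "csv") {
    utils::write.table(df, path, sep = dialect$sep, row.names = FALSE,
                       quote = FALSE)
  } else {
    cols <- vapply(seq_along(df), function(j) {
      max(nchar(c(names(df)[j], as.character(df[[j]]))))
    }, integer(1))
    pad <- function(v, w) vapply(seq_along(v), function(j)
      formatC(v[j], width = w[j], flag = "-"), character(1))
    lines <- c(
      paste0("| ", paste(pad(names(df), cols), collapse = " | "), " |"),
      paste0("|", paste(strrep("-", cols + 2), collapse = "|"), "|"),
      apply(df, 1, function(r)
        paste0("| ", paste(pad(as.character(r), cols), collapse = " | "), " |"))
    )
    writeLines(lines, path)
  }
  invisible(path)
}
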