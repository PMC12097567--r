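#' Read a run configuration
#'
#' The configuration is a plain YAML file with the inputs and knobs of a
#' full report run:
#'
#' ```yaml
#' composition:              # one entry per attribute panel
#'   age: panels/age.csv
#'   education: panels/education.csv
#' baseline:                 # optional, per-attribute baseline share CSVs
#'   age: panels/age_baseline.csv
#' factors: panels/factors.csv
#' reference: oral_health_workforce   # reference column in the factor file
#' rho: 0.5
#' normalization: initial_value
#' sep: ","
#' out_dir: results
#' ```
#'
#' @param path path to a YAML config file.
#' @return a `run_config` list with defaults filled in.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  run_config(composition = raw$composition,
             factors = raw$factors,
             baseline = raw$baseline,
             reference = raw$reference,
             rho = raw$rho %||% 0.5,
             normalization = raw$normalization %||% "initial_value",
             sep = raw$sep %||% ",",
             out_dir = raw$out_dir %||% ".")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a run configuration in code
#'
#' @param composition named list of composition-panel file paths, one per
#'   attribute.
#' @param factors path to the factor-panel file.
#' @param baseline optional named list of baseline CSVs (a single row of
#'   shares for the year preceding each panel); names must match
#'   `composition`.
#' @param reference reference column name in the factor file (default:
#'   first data column).
#' @param rho,normalization see [grey_config()].
#' @param sep field delimiter for all files.
#' @param out_dir output directory for result tables and the manifest.
#' @return a `run_config` list.
#' @export
run_config <- function(composition, factors, baseline = NULL,
                       reference = NULL, rho = 0.5,
                       normalization = "initial_value", sep = ",",
                       out_dir = ".") {
  if (is.null(composition) || length(composition) == 0) {
    stop("config must name at least one composition panel", call. = FALSE)
  }
  if (is.null(factors)) {
    stop("config must name a factor panel file", call. = FALSE)
  }
  structure(list(composition = composition, factors = factors,
                 baseline = baseline, reference = reference,
                 grey = grey_config(rho = rho, normalization = normalization),
                 dialect = table_dialect(sep = sep),
                 out_dir = out_dir),
            class = "run_config")
}

#' Run both analyses end to end and write all result tables
#'
#' For every composition panel in the config, runs the structural change
#' analysis and writes one result table; runs the grey relational analysis
#' on the factor panel and writes its table; and writes a `manifest.json`
#' (config echo, package version, input checksums) sufficient to reproduce
#' the run. Identical inputs and config produce byte-identical outputs.
#'
#' @param config a `run_config` from [run_config()] or [read_run_config()],
#'   or a path to a YAML config file.
#' @param quiet suppress progress messages.
#' @return invisibly, a named character vector of the files written.
#' @export
run_report <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  inputs <- c(unlist(config$composition), factors = config$factors,
              unlist(config$baseline))
  missing <- inputs[!file.exists(inputs)]
  if (length(missing) > 0) {
    stop(sprintf("missing input file(s): %s",
                 paste(sprintf("%s (%s)", missing, names(missing)),
                       collapse = ", ")), call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)

  for (attr_name in names(config$composition)) {
    stage <- sprintf("structural-change[%s]", attr_name)
    res <- tryCatch({
      panel <- read_composition_panel(config$composition[[attr_name]],
                                      config$dialect,
                                      attribute = attr_name)
      baseline <- NULL
      if (!is.null(config$baseline[[attr_name]])) {
        bdf <- utils::read.table(config$baseline[[attr_name]], header = TRUE,
                                 sep = config$dialect$sep,
                                 check.names = FALSE)
        baseline <- as.numeric(bdf[1, panel$categories])
      }
      run_structural_change(panel, baseline)
    }, error = function(e) {
      stop(sprintf("stage %s failed on input '%s': %s", stage,
                   config$composition[[attr_name]], conditionMessage(e)),
           call. = FALSE)
    })
    out <- file.path(config$out_dir,
                     sprintf("structural_change_%s.csv", attr_name))
    write_result_table(res, out, config$dialect)
    written[stage] <- out
    say("wrote %s", out)
  }

  gra <- tryCatch({
    fp <- read_factor_panel(config$factors, config$dialect,
                            reference = config$reference)
    run_gra(fp, config$grey)
  }, error = function(e) {
    stop(sprintf("stage grey-relational failed on input '%s': %s",
                 config$factors, conditionMessage(e)), call. = FALSE)
  })
  out <- file.path(config$out_dir, "grey_relational.csv")
  write_result_table(gra, out, config$dialect)
  written["grey-relational"] <- out
  say("wrote %s", out)
  say("config used: rho = %g, normalization = %s, baseline panels: %s",
      config$grey$rho, config$grey$normalization,
      if (length(config$baseline) > 0)
        paste(names(config$baseline), collapse = ", ") else "none")

  manifest <- list(
    package = "greyhealth",
    version = as.character(utils::packageVersion("greyhealth")),
    config = list(
      composition = as.list(config$composition),
      baseline = as.list(config$baseline %||% list()),
      factors = config$factors,
      reference = config$reference %||% "(first data column)",
      rho = config$grey$rho,
      normalization = config$grey$normalization,
      sep = config$dialect$sep,
      out_dir = config$out_dir),
    input_md5 = as.list(tools::md5sum(unname(inputs))),
    outputs = as.list(written)
  )
  mpath <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  written["manifest"] <- mpath
  say("wrote %s", mpath)
  invisible(written)
}
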