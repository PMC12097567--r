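#' Published reference values for China's oral-health workforce, 2017-2022
#'
#' Bundled copies of the published structural-change analyses (one per
#' workforce attribute: age, work experience, educational qualification,
#' professional/technical qualification) and of the published grey
#' relational coefficients, degrees and ranks for the eight candidate
#' drivers. Each structural-change table carries the signed change values
#' (`scv_*`, fractions), the degree (`scd`, %) and the contribution rates
#' (`scc_*`, %) as printed. These serve as ground truth for
#' internal-consistency checks: recomputing degree and contribution rates
#' from the printed change values reproduces the printed cells.
#'
#' @param table one of `"age"`, `"experience"`, `"education"`,
#'   `"qualification"`, `"gra_coefficients"`, `"gra_degrees"`.
#' @return a data.frame of the published values.
#' @export
published_table <- function(table = c("age", "experience", "education",
                                      "qualification", "gra_coefficients",
                                      "gra_degrees")) {
  table <- match.arg(table)
  file <- if (startsWith(table, "gra")) {
    sprintf("published_%s.csv", table)
  } else {
    sprintf("published_scv_%s.csv", table)
  }
  path <- system.file("extdata", file, package = "greyhealth")
  utils::read.csv(path, check.names = FALSE)
}
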