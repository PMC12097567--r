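#' Specification for synthetic panel generation
#'
#' Describes the statistical shape of the panels the generator emulates:
#' a short annual composition series with smooth per-category trends, and a
#' set of positive driver series whose association with a growing reference
#' series is controlled per factor. Defaults mirror a six-year national
#' workforce panel with eight candidate drivers.
#'
#' @param n_years number of years (>= 2); default 6.
#' @param start_year first calendar year; default 2017.
#' @param categories category labels for the composition panel.
#' @param start_shares starting percentage shares, summing to 100.
#' @param drift per-category annual drift in percentage points per year
#'   (signed); default all zero.
#' @param share_noise standard deviation of share noise on the logistic
#'   scale (dimensionless); default 0.05. Zero gives deterministic shares.
#' @param n_factors number of comparison series; default 8.
#' @param ref_growth annual exponential growth rate of the reference
#'   series; default 0.05 (5%/yr, the order of magnitude of national
#'   workforce growth).
#' @param factor_growth annual growth rates of the factors' independent
#'   components; default evenly spread over 0.02--0.16.
#' @param association per-factor weight in [0, 1] blending the reference's
#'   normalized shape (weight `association`) with the factor's independent
#'   shape; 1 means the factor tracks the reference exactly. Default 0.3.
#' @param factor_noise standard deviation of multiplicative log-normal
#'   noise on factor levels; default 0.02.
#' @param seed integer seed; one seed governs the whole generator.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_years = 6L,
                           start_year = 2017L,
                           categories = paste0("category_", 1:6),
                           start_shares = c(3, 33, 33, 18, 7, 6),
                           drift = rep(0, length(categories)),
                           share_noise = 0.05,
                           n_factors = 8L,
                           ref_growth = 0.05,
                           factor_growth = seq(0.02, 0.16,
                                               length.out = n_factors),
                           association = rep(0.3, n_factors),
                           factor_noise = 0.02,
                           seed = 1L) {
  stopifnot(n_years >= 2,
            length(start_shares) == length(categories),
            length(drift) == length(categories),
            share_noise >= 0, factor_noise >= 0,
            n_factors >= 1,
            length(factor_growth) == n_factors,
            length(association) == n_factors,
            all(association >= 0 & association <= 1))
  if (abs(sum(start_shares) - 100) > 1e-8) {
    stop("start_shares must sum to 100", call. = FALSE)
  }
  structure(list(n_years = as.integer(n_years),
                 start_year = as.integer(start_year),
                 categories = categories,
                 start_shares = start_shares,
                 drift = drift,
                 share_noise = share_noise,
                 n_factors = as.integer(n_factors),
                 ref_growth = ref_growth,
                 factor_growth = factor_growth,
                 association = association,
                 factor_noise = factor_noise,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# run expr under a private random stream seeded with `seed`,
# leaving the caller's .Random.seed untouched
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic composition panel
#'
#' Shares follow linear percentage-point trends (`start_shares + drift *
#' t`), perturbed by Gaussian noise on the logistic scale and renormalized
#' so every row sums to exactly 100 and stays inside (0, 100). With zero
#' drift and zero noise the panel is constant; with drifts summing to zero
#' and zero noise every period's structural change values equal
#' `drift / 100` exactly.
#'
#' @param spec a [synthetic_spec()].
#' @param attribute attribute name for the generated panel.
#' @return a validated [composition_panel()], deterministic given the seed.
#' @export
generate_composition_panel <- function(spec, attribute = "synthetic") {
  t_idx <- seq_len(spec$n_years) - 1
  mu <- outer(t_idx, spec$drift) +
    matrix(spec$start_shares, spec$n_years, length(spec$categories),
           byrow = TRUE)
  if (any(mu <= 0 | mu >= 100)) {
    stop("infeasible drift: a category's trend share leaves (0, 100) within the horizon",
         call. = FALSE)
  }
  shares <- with_seed(spec$seed, {
    p <- mu / 100
    z <- log(p / (1 - p)) +
      matrix(stats::rnorm(length(p), sd = spec$share_noise), nrow(p))
    q <- 100 * (1 / (1 + exp(-z)))
    100 * q / rowSums(q)
  })
  colnames(shares) <- spec$categories
  composition_panel(shares, spec$start_year + t_idx, attribute = attribute)
}

#' Generate a synthetic factor panel
#'
#' The reference is a smooth exponential growth series. Factor i blends the
#' reference's normalized shape (weight `association[i]`) with an
#' independent smooth growth shape (weight `1 - association[i]`), rescales
#' to its own level and applies multiplicative log-normal noise, keeping
#' every series strictly positive. A factor with association 1 and zero
#' noise is exactly proportional to the reference and attains relational
#' degree 1.
#'
#' @param spec a [synthetic_spec()].
#' @return a validated [factor_panel()], deterministic given the seed.
#' @export
generate_factor_panel <- function(spec) {
  t_idx <- seq_len(spec$n_years) - 1
  reference <- 1000 * exp(spec$ref_growth * t_idx)
  ref_shape <- reference / reference[1]
  comparisons <- with_seed(spec$seed + 1L, {
    t(vapply(seq_len(spec$n_factors), function(i) {
      own_shape <- exp(spec$factor_growth[i] * t_idx)
      shape <- spec$association[i] * ref_shape +
        (1 - spec$association[i]) * own_shape
      level <- 100 * i
      for (attempt in 1:10) {
        x <- level * shape * exp(stats::rnorm(spec$n_years,
                                              sd = spec$factor_noise))
        if (all(x > 0)) return(x)
      }
      stop(sprintf("could not generate a positive series for factor %d", i),
           call. = FALSE)
    }, numeric(spec$n_years)))
  })
  rownames(comparisons) <- paste0("factor_", seq_len(spec$n_factors))
  factor_panel(spec$start_year + t_idx, reference, comparisons,
               reference_name = "reference")
}

#' Deterministic workforce-shaped fixture
#'
#' Builds the fixture used across the test suite: four composition panels
#' with the dimensions of a national oral-health workforce panel — age (6
#' bands), years of work experience (5 bands), educational qualification
#' (5 levels), professional/technical qualification (6 levels) — over the
#' six years 2017--2022, plus a factor panel with the eight-driver roster
#' (population, ageing, dependency, urbanization, GDP, income, health
#' expenditure, expenditure/GDP ratio). Values are synthetic; only the
#' shape matches the published panels.
#'
#' @param seed integer seed (default 20170601).
#' @return list with elements `age`, `experience`, `education`,
#'   `qualification` (composition panels) and `factors` (a factor panel).
#' @export
workforce_fixture <- function(seed = 20170601L) {
  panels <- list(
    age = synthetic_spec(
      categories = c("under_25", "age_25_34", "age_35_44", "age_45_54",
                     "age_55_59", "age_60_plus"),
      start_shares = c(2, 31, 33, 19, 8, 7),
      drift = c(0.2, 0.8, -0.2, -0.5, -0.2, -0.1),
      seed = seed),
    experience = synthetic_spec(
      categories = c("under_5y", "exp_5_9y", "exp_10_19y", "exp_20_29y",
                     "exp_30y_plus"),
      start_shares = c(24, 20, 26, 19, 11),
      drift = c(1.0, 0.2, -0.4, -0.5, -0.3),
      seed = seed + 1L),
    education = synthetic_spec(
      categories = c("postgraduate", "undergraduate", "college",
                     "junior_college", "high_school_or_below"),
      start_shares = c(7, 31, 39, 19, 4),
      drift = c(0.3, 0.8, 0.6, -1.5, -0.2),
      seed = seed + 2L),
    qualification = synthetic_spec(
      categories = c("senior", "associate_senior", "intermediate",
                     "division_assistant", "bachelor_level", "unspecified"),
      start_shares = c(3, 7, 23, 47, 14, 6),
      drift = c(0.0, 0.1, 0.2, 0.5, 0.1, -0.9),
      seed = seed + 3L)
  )
  comps <- lapply(names(panels), function(nm)
    generate_composition_panel(panels[[nm]], attribute = nm))
  names(comps) <- names(panels)

  fspec <- synthetic_spec(
    association = c(0.2, 0.5, 0.4, 0.3, 0.6, 0.7, 0.9, 0.4),
    seed = seed + 4L)
  factors <- generate_factor_panel(fspec)
  rownames(factors$comparisons) <- factors$comparison_names <-
    c("resident_population", "pct_aged_65_plus", "dependency_ratio",
      "urbanization_level", "per_capita_gdp",
      "per_capita_disposable_income", "per_capita_health_expenditure",
      "health_expenditure_gdp_ratio")
  factors$reference_name <- "oral_health_workforce"

  c(comps, list(factors = factors))
}
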