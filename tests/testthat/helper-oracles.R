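# Independent brute-force oracles and ad-hoc input builders.
# These deliberately use explicit loops and no package internals, so they
# stay independent of the implementation they check.

# random composition panel: rows drawn uniform then renormalized to 100
random_panel <- function(n_years = 6, n_cat = 5, start_year = 2017) {
  shares <- matrix(runif(n_years * n_cat, 5, 40), n_years, n_cat)
  shares <- 100 * shares / rowSums(shares)
  colnames(shares) <- paste0("c", seq_len(n_cat))
  composition_panel(shares, start_year + seq_len(n_years) - 1)
}

# random strictly-positive factor panel
random_factor_panel <- function(n_years = 6, m = 8, start_year = 2017) {
  comp <- matrix(exp(rnorm(m * n_years, 5, 1)), m, n_years)
  rownames(comp) <- paste0("f", seq_len(m))
  factor_panel(start_year + seq_len(n_years) - 1,
               exp(rnorm(n_years, 7, 0.5)), comp)
}

# first-differences oracle: loops over years and categories
oracle_scv <- function(shares) {
  n <- nrow(shares); m <- ncol(shares)
  out <- matrix(NA_real_, n - 1, m)
  for (t in 2:n) for (j in 1:m) {
    out[t - 1, j] <- (shares[t, j] - shares[t - 1, j]) / 100
  }
  out
}

oracle_scd <- function(scv_row) {
  s <- 0
  for (v in scv_row) s <- s + abs(v)
  100 * s
}

oracle_scc <- function(scv_row) {
  total <- oracle_scd(scv_row) / 100
  out <- numeric(length(scv_row))
  if (total == 0) return(out)
  for (j in seq_along(scv_row)) out[j] <- 100 * abs(scv_row[j]) / total
  out
}

# full GRA by explicit double loops (initial-value normalization)
oracle_gra_degrees <- function(reference, comparisons, rho = 0.5) {
  n <- length(reference); m <- nrow(comparisons)
  r0 <- numeric(n)
  for (k in 1:n) r0[k] <- reference[k] / reference[1]
  delta <- matrix(NA_real_, m, n)
  for (i in 1:m) for (k in 1:n) {
    delta[i, k] <- abs(r0[k] - comparisons[i, k] / comparisons[i, 1])
  }
  dmin <- Inf; dmax <- -Inf
  for (i in 1:m) for (k in 1:n) {
    if (delta[i, k] < dmin) dmin <- delta[i, k]
    if (delta[i, k] > dmax) dmax <- delta[i, k]
  }
  degrees <- numeric(m)
  for (i in 1:m) {
    acc <- 0
    for (k in 1:n) {
      acc <- acc + (dmin + rho * dmax) / (delta[i, k] + rho * dmax)
    }
    degrees[i] <- acc / n
  }
  degrees
}
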