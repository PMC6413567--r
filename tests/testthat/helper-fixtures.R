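# shared fixtures: scaled-down cohorts and fast sampler settings

# default five-country design with n subjects per country
scaled_countries <- function(n_per_country) {
  lapply(default_countries(), function(s) {
    s$n_subjects <- as.integer(n_per_country)
    s
  })
}

# countries with no seasonality (optionally no effect), for clean checks
flat_countries <- function(n_per_country = 50L, n_countries = 3L,
                           baseline = 80, effect = 20) {
  lapply(seq_len(n_countries), function(k)
    country_spec(paste0("C", k), n_per_country, baseline, effect))
}

fast_spec <- function(...) {
  model_spec(chains = 2L, adapt = 200L, warmup = 200L, draws = 400L,
             n_repeats = 1L, ...)
}

# independent empirical-quantile oracle (linear interpolation, as in the
# classic sorted-order-statistics formula h = (n-1)p + 1)
quantile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}
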