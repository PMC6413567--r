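#' Specification of one country in a synthetic cohort
#'
#' Describes the generating values for a single recruitment country: how many
#' subjects it contributes, its mean baseline adherence index, the mean shift
#' produced by the intervention at follow-up, and the two weights of the
#' yearly sinusoidal seasonality term (see [seasonal_value()]).
#'
#' @param name Country label.
#' @param n_subjects Number of subjects recruited in this country.
#' @param baseline_mean Mean true baseline index, on the 0-160 point scale.
#' @param effect_mean Mean intervention effect (points added at follow-up for
#'   the intervention arm).
#' @param seasonal_weight_sin,seasonal_weight_cos Weights of the sine and
#'   cosine components of the yearly oscillation, in index points. The
#'   half-range (amplitude) of the oscillation is
#'   `sqrt(seasonal_weight_sin^2 + seasonal_weight_cos^2)`.
#'
#' @return An object of class `"country_spec"`.
#' @seealso [default_countries()], [cohort_config()]
#' @export
country_spec <- function(name, n_subjects, baseline_mean, effect_mean = 0,
                         seasonal_weight_sin = 0, seasonal_weight_cos = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects <= 0L)
    stop("'n_subjects' must be a positive integer", call. = FALSE)
  if (!is.finite(baseline_mean) || baseline_mean < 0 || baseline_mean > 160)
    stop("'baseline_mean' must lie in [0, 160]", call. = FALSE)
  amp <- sqrt(seasonal_weight_sin^2 + seasonal_weight_cos^2)
  if (amp > baseline_mean)
    stop("seasonal amplitude exceeds 'baseline_mean'", call. = FALSE)
  structure(
    list(name = name, n_subjects = n_subjects,
         baseline_mean = baseline_mean, effect_mean = effect_mean,
         seasonal_weight_sin = seasonal_weight_sin,
         seasonal_weight_cos = seasonal_weight_cos),
    class = "country_spec")
}

#' Default five-country generating configuration
#'
#' The default cohort emulates a 1,133-subject, five-country, two-arm dietary
#' intervention trial: per-country sample sizes 241/251/235/222/184, a common
#' baseline of 80 points (with one country, NL, offset to 87), a 20-point
#' intervention effect in four countries and an almost-double (38-point)
#' effect in the outlier country (FR), and country-specific yearly
#' seasonality with peak-to-trough differences of 4 points in the two
#' high-seasonality countries (FR, PL), 2.5 in IT and 1 in UK and NL.
#'
#' Peak timing is a documented convention (late spring/summer peaks for the
#' high-seasonality countries); only the amplitude ordering matters for the
#' recovery experiments shipped with the package.
#'
#' @return A list of [country_spec()] objects.
#' @export
default_countries <- function() {
  p2t  <- c(IT = 2.5, UK = 1, NL = 1, PL = 4, FR = 4)
  peak <- c(IT = 0.50, UK = 0.25, NL = 0.25, PL = 0.55, FR = 0.60)
  n    <- c(IT = 241, UK = 251, NL = 235, PL = 222, FR = 184)
  base <- c(IT = 80, UK = 80, NL = 87, PL = 80, FR = 80)
  eff  <- c(IT = 20, UK = 20, NL = 20, PL = 20, FR = 38)
  amp  <- p2t / 2
  lapply(names(n), function(k)
    country_spec(k, n[[k]], base[[k]], eff[[k]],
                 seasonal_weight_sin = amp[[k]] * sin(2 * pi * peak[[k]]),
                 seasonal_weight_cos = amp[[k]] * cos(2 * pi * peak[[k]])))
}

#' Configuration of the synthetic cohort generator
#'
#' Bundles the country specifications with the population-level variance
#' components and design settings of a two-visit, two-arm trial.
#'
#' Defaults follow the structure the hierarchical model assumes: a
#' measurement (within-subject) SD of 16 points, i.e. 20% of the 80-point
#' baseline; a between-subject SD such that the within/between ratio is 1.03;
#' subject-level intervention effects spread around the country mean with an
#' SD equal to the between-subject SD (matching the null model's assumption
#' that the between-visit variation is distributed like the baseline spread);
#' controls experiencing 5% of the country effect as a participation drift;
#' recruitment uniform over the calendar year with the follow-up visit 10-14
#' months later.
#'
#' @param countries List of [country_spec()] objects.
#' @param sigma_between Between-subject SD of the true baseline (points).
#' @param sigma_meas Within-subject (measurement) SD per visit (points).
#' @param sigma_effect SD of subject-level intervention effects around the
#'   country mean effect (points).
#' @param control_drift_fraction Fraction of the country effect experienced
#'   by control subjects through study participation alone, in `[0, 1]`.
#' @param include_between_visit_change If `TRUE`, adds an extra `N(0,
#'   change_sd)` true change between visits to every subject (the null
#'   model's between-visit variation). Off by default: the cohort generator
#'   assumes stable controls.
#' @param change_sd SD of the optional between-visit change (points).
#' @param visit_gap_months Length-2 numeric, range of the follow-up gap in
#'   months (drawn uniformly).
#' @param date_sampling `"uniform"` (recruitment uniform over the year) or
#'   `"fixed"` (all baseline visits at `fixed_date_fraction`).
#' @param fixed_date_fraction Year fraction used when `date_sampling =
#'   "fixed"`.
#' @param clip_scores If `TRUE`, observed scores are clipped to `[0, 160]`.
#'   Off by default: the observation model is Normal and clipping would bias
#'   variance estimates.
#' @param seed Optional integer seed stored with the configuration.
#'
#' @return An object of class `"cohort_config"`.
#' @export
cohort_config <- function(countries = default_countries(),
                          sigma_between = 16 / 1.03,
                          sigma_meas = 16,
                          sigma_effect = sigma_between,
                          control_drift_fraction = 0.05,
                          include_between_visit_change = FALSE,
                          change_sd = 0,
                          visit_gap_months = c(10, 14),
                          date_sampling = c("uniform", "fixed"),
                          fixed_date_fraction = 0,
                          clip_scores = FALSE,
                          seed = NULL) {
  if (!is.list(countries) || length(countries) == 0L)
    stop("'countries' must be a non-empty list of country_spec objects",
         call. = FALSE)
  if (!all(vapply(countries, inherits, logical(1), "country_spec")))
    stop("every element of 'countries' must be a country_spec", call. = FALSE)
  for (s in list(sigma_between = sigma_between, sigma_meas = sigma_meas,
                 sigma_effect = sigma_effect, change_sd = change_sd)) {
    if (!is.finite(s) || s < 0)
      stop("all standard deviations must be finite and >= 0", call. = FALSE)
  }
  if (control_drift_fraction < 0 || control_drift_fraction > 1)
    stop("'control_drift_fraction' must lie in [0, 1]", call. = FALSE)
  stopifnot(length(visit_gap_months) == 2L,
            all(is.finite(visit_gap_months)),
            visit_gap_months[1] <= visit_gap_months[2])
  date_sampling <- match.arg(date_sampling)
  structure(
    list(countries = countries, sigma_between = sigma_between,
         sigma_meas = sigma_meas, sigma_effect = sigma_effect,
         control_drift_fraction = control_drift_fraction,
         include_between_visit_change = include_between_visit_change,
         change_sd = change_sd, visit_gap_months = visit_gap_months,
         date_sampling = date_sampling,
         fixed_date_fraction = fixed_date_fraction,
         clip_scores = clip_scores, seed = seed),
    class = "cohort_config")
}

#' Yearly sinusoidal seasonality term
#'
#' Evaluates the additive seasonal modulation of the adherence index,
#' `weight_sin * sin(2*pi*t) + weight_cos * cos(2*pi*t)`, a single yearly
#' harmonic whose amplitude (half-range) is `sqrt(weight_sin^2 +
#' weight_cos^2)` and whose peak falls at year fraction
#' `atan2(weight_sin, weight_cos) / (2*pi)` (mod 1). The mean over a full
#' year is zero, so the term shifts the expected index around the yearly
#' average without changing it.
#'
#' @param weight_sin,weight_cos Oscillation weights in index points.
#' @param t Year fraction; values outside `[0, 1)` wrap by periodicity.
#' @return Seasonal offset in index points (vectorised over any argument).
#' @examples
#' seasonal_value(3, 4, atan2(3, 4) / (2 * pi))  # peak value = 5
#' @export
seasonal_value <- function(weight_sin, weight_cos, t) {
  stopifnot(all(is.finite(t)))
  weight_sin * sin(2 * pi * t) + weight_cos * cos(2 * pi * t)
}

#' Convert calendar dates to year fractions
#'
#' Maps a date to `(day_of_year - 1) / 365.25`, the half-open `[0, 1)`
#' parametrisation used by the seasonality term (1 January maps to 0).
#'
#' @param dates A `Date` vector (or something coercible by [as.Date()]).
#' @return Numeric vector of year fractions in `[0, 1)`.
#' @export
date_fraction <- function(dates) {
  d <- as.Date(dates)
  (as.integer(strftime(d, "%j")) - 1) / 365.25
}

#' Generate a synthetic two-visit, two-arm cohort
#'
#' Draws a cohort with the generative structure the hierarchical model
#' assumes. For subject i in country c with true baseline `b_i ~
#' N(baseline_mean_c, sigma_between)`, the observed scores are
#' \deqn{y_{T0} = b_i + season_c(t_0) + e_0, \qquad
#'       y_{T1} = b_i + d_i + season_c(t_1) + e_1,}
#' with `e ~ N(0, sigma_meas)` i.i.d. per visit. Intervention subjects have
#' `d_i ~ N(effect_mean_c, sigma_effect)`; controls have `d_i =
#' control_drift_fraction * effect_mean_c` (plus the optional between-visit
#' change noise when enabled). Arms are assigned by balanced randomisation
#' within country. Output is deterministic given the seed.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A list of class `"cohort"` with components
#'   \describe{
#'     \item{records}{data frame, one row per visit: `subject_id`, `country`,
#'       `arm`, `visit` (`"T0"`/`"T1"`), `date_fraction`, `observed_score`.}
#'     \item{truth}{data frame, one row per subject, with the latent
#'       generating values: `true_baseline`, `true_effect`, `t0_fraction`,
#'       `t1_fraction`, `t1_elapsed_years`.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
generate_cohort <- function(config, seed = config$seed) {
  if (!inherits(config, "cohort_config"))
    stop("'config' must be a cohort_config object", call. = FALSE)
  if (is.null(seed))
    stop("a seed is required for reproducible generation", call. = FALSE)
  set.seed(as.integer(seed))

  specs <- config$countries
  n_c <- vapply(specs, `[[`, integer(1), "n_subjects")
  cname <- vapply(specs, `[[`, character(1), "name")
  N <- sum(n_c)

  country <- rep(cname, n_c)
  subject_id <- sprintf("S%04d", seq_len(N))

  ## balanced randomisation within country
  arm <- unlist(lapply(n_c, function(k)
    sample(rep(c("control", "intervention"), length.out = k))),
    use.names = FALSE)

  base_mean <- rep(vapply(specs, `[[`, numeric(1), "baseline_mean"), n_c)
  eff_mean  <- rep(vapply(specs, `[[`, numeric(1), "effect_mean"), n_c)
  w_sin <- rep(vapply(specs, `[[`, numeric(1), "seasonal_weight_sin"), n_c)
  w_cos <- rep(vapply(specs, `[[`, numeric(1), "seasonal_weight_cos"), n_c)

  true_baseline <- stats::rnorm(N, base_mean, config$sigma_between)
  interv <- arm == "intervention"
  true_effect <- ifelse(interv,
                        stats::rnorm(N, eff_mean, config$sigma_effect),
                        config$control_drift_fraction * eff_mean)
  if (config$include_between_visit_change && config$change_sd > 0)
    true_effect <- true_effect + stats::rnorm(N, 0, config$change_sd)

  t0 <- if (config$date_sampling == "uniform") stats::runif(N)
        else rep(config$fixed_date_fraction, N)
  gap_years <- stats::runif(N, config$visit_gap_months[1],
                            config$visit_gap_months[2]) / 12
  t1 <- (t0 + gap_years) %% 1

  y0 <- true_baseline + seasonal_value(w_sin, w_cos, t0) +
    stats::rnorm(N, 0, config$sigma_meas)
  y1 <- true_baseline + true_effect + seasonal_value(w_sin, w_cos, t1) +
    stats::rnorm(N, 0, config$sigma_meas)
  if (config$clip_scores) {
    y0 <- pmin(pmax(y0, 0), 160)
    y1 <- pmin(pmax(y1, 0), 160)
  }

  records <- data.frame(
    subject_id = rep(subject_id, 2L),
    country = rep(country, 2L),
    arm = rep(arm, 2L),
    visit = rep(c("T0", "T1"), each = N),
    date_fraction = c(t0, t1),
    observed_score = c(y0, y1),
    stringsAsFactors = FALSE)
  ## interleave so both visits of a subject are adjacent
  records <- records[order(match(records$subject_id, subject_id),
                           records$visit), , drop = FALSE]
  rownames(records) <- NULL

  truth <- data.frame(
    subject_id = subject_id, country = country, arm = arm,
    true_baseline = true_baseline, true_effect = true_effect,
    t0_fraction = t0, t1_fraction = t1, t1_elapsed_years = gap_years,
    stringsAsFactors = FALSE)

  structure(list(records = records, truth = truth, config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  n <- nrow(x$truth)
  cat("Synthetic two-visit cohort:", n, "subjects,",
      nrow(x$records), "visit records\n")
  tab <- table(x$truth$country, x$truth$arm)
  print(tab)
  invisible(x)
}
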