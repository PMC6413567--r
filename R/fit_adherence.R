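#' Assemble model-ready arrays from visit records
#'
#' Validates a two-visit cohort table and reshapes it into the index arrays
#' the sampler consumes: one row per subject with both observed scores,
#' country and arm index maps, and the sine/cosine of the visit dates'
#' year fractions.
#'
#' @param records Visit-records data frame with columns `subject_id`,
#'   `country`, `arm` (`"control"`/`"intervention"`), `visit`
#'   (`"T0"`/`"T1"`), `date_fraction` and `observed_score`.
#' @return An object of class `"adherence_inputs"`: list with `subject_id`,
#'   `country_levels`, `country_idx`, `intervention` (0/1), `y0`, `y1`,
#'   `t0`, `t1`, `n_subjects`, `n_countries`.
#' @export
build_inputs <- function(records) {
  req <- c("subject_id", "country", "arm", "visit", "date_fraction",
           "observed_score")
  if (!all(req %in% names(records)))
    stop("'records' must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  bad_arm <- setdiff(unique(records$arm), c("control", "intervention"))
  if (length(bad_arm))
    stop("unknown arm label(s): ", paste(bad_arm, collapse = ", "),
         call. = FALSE)
  wide <- .pair_visits(records)   # errors on duplicated or missing visits
  country_levels <- sort(unique(wide$country))
  structure(list(
    subject_id = wide$subject_id,
    country_levels = country_levels,
    country_idx = match(wide$country, country_levels),
    arm = wide$arm,
    intervention = as.integer(wide$arm == "intervention"),
    y0 = wide$t0, y1 = wide$t1,
    t0 = wide$t0_fraction, t1 = wide$t1_fraction,
    n_subjects = nrow(wide), n_countries = length(country_levels)),
    class = "adherence_inputs")
}

#' Prior, likelihood and sampler settings for the hierarchical model
#'
#' All priors are weakly informative on the 0-160 index scale and every
#' constant is exposed here. Country baseline centres get independent
#' `Normal(80, 20)` priors (a single hierarchical layer: pooling subjects
#' within countries but not baselines across countries, which keeps an
#' outlying country from destabilising the rest). The intervention effect
#' is a two-layer hierarchy: global effect `Normal(0, 20)`, country effects
#' drawn around it, subject effects drawn around their country's. All
#' standard deviations get half-Normal(0, 20) priors; seasonal weights are
#' hierarchical around shared weights with Normal(0, 5) scales.
#'
#' @param baseline_center_loc,baseline_center_scale Prior on each country
#'   baseline centre (points).
#' @param effect_loc,effect_scale Prior on the global intervention effect.
#' @param sd_prior_scale Half-Normal scale for `sigma_meas`,
#'   `sigma_between`, `sigma_effect` and `sigma_country` (points).
#' @param seasonal_weight_scale Half-Normal scale of the across-country SD
#'   of seasonal weights, and Normal scale of the shared weights (points).
#' @param robust_effects If `TRUE`, country effects get a Student-t
#'   distribution around the global effect (an outlier-robustness toggle);
#'   default `FALSE`.
#' @param effect_df Degrees of freedom for the robust country-effect
#'   distribution.
#' @param control_drift Fraction of the subject effect experienced by
#'   controls (participation drift); fixed at 0.05 by default.
#' @param estimate_drift If `TRUE`, the drift is estimated under a tight
#'   `Normal(control_drift, drift_prior_sd)` prior truncated to `[0, 1]`.
#' @param drift_prior_sd Prior SD for the estimated drift.
#' @param sigma_meas_fixed Optional: fix the measurement SD at this value
#'   instead of estimating it (useful for noise-free checks).
#' @param chains,adapt,warmup,draws MCMC settings per repeat: number of
#'   chains, adaptation steps, post-adaptation burn-in, and retained draws
#'   per chain.
#' @param n_repeats Independent seeded re-runs of the sampler (default 5);
#'   per-repeat posterior means are reported side by side as a stability
#'   check and draws are pooled for the final summaries.
#' @return An object of class `"model_spec"`.
#' @export
model_spec <- function(baseline_center_loc = 80,
                       baseline_center_scale = 20,
                       effect_loc = 0, effect_scale = 20,
                       sd_prior_scale = 20,
                       seasonal_weight_scale = 5,
                       robust_effects = FALSE, effect_df = 4,
                       control_drift = 0.05,
                       estimate_drift = FALSE, drift_prior_sd = 0.02,
                       sigma_meas_fixed = NULL,
                       chains = 2L, adapt = 500L, warmup = 500L,
                       draws = 1000L, n_repeats = 5L) {
  for (s in list(baseline_center_scale, effect_scale, sd_prior_scale,
                 seasonal_weight_scale, drift_prior_sd))
    if (!is.finite(s) || s <= 0)
      stop("prior scales must be positive", call. = FALSE)
  if (!is.null(sigma_meas_fixed) &&
      (!is.finite(sigma_meas_fixed) || sigma_meas_fixed <= 0))
    stop("'sigma_meas_fixed' must be positive", call. = FALSE)
  n_repeats <- as.integer(n_repeats)
  if (is.na(n_repeats) || n_repeats < 1L)
    stop("'n_repeats' must be >= 1", call. = FALSE)
  structure(list(
    baseline_center_loc = baseline_center_loc,
    baseline_center_scale = baseline_center_scale,
    effect_loc = effect_loc, effect_scale = effect_scale,
    sd_prior_scale = sd_prior_scale,
    seasonal_weight_scale = seasonal_weight_scale,
    robust_effects = isTRUE(robust_effects), effect_df = effect_df,
    control_drift = control_drift,
    estimate_drift = isTRUE(estimate_drift),
    drift_prior_sd = drift_prior_sd,
    sigma_meas_fixed = sigma_meas_fixed,
    chains = as.integer(chains), adapt = as.integer(adapt),
    warmup = as.integer(warmup), draws = as.integer(draws),
    n_repeats = n_repeats),
    class = "model_spec")
}

## JAGS source for the hierarchical observation model. Centered
## parametrization throughout: with a Normal likelihood and Normal priors
## every location parameter keeps a conjugate full conditional, which is
## what makes Gibbs sampling efficient here.
.jags_model_string <- function(spec) {
  sigma_m_line <- if (is.null(spec$sigma_meas_fixed))
    "sigma_meas ~ dnorm(0, sd_prec) T(0,)"
  else
    "sigma_meas <- sigma_meas_fixed"
  drift_line <- if (spec$estimate_drift)
    "drift ~ dnorm(drift_loc, drift_prec) T(0, 1)"
  else
    "drift <- drift_loc"
  dc_line <- if (spec$robust_effects)
    "Dc[k] ~ dt(D, tau_country, effect_df)"
  else
    "Dc[k] ~ dnorm(D, tau_country)"
  paste0("
model {
  for (i in 1:N) {
    b[i] ~ dnorm(B[country[i]], tau_between)
    d[i] ~ dnorm(Dc[country[i]], tau_effect)
    scale_i[i] <- intervention[i] + (1 - intervention[i]) * drift
    y0[i] ~ dnorm(b[i] + ws[country[i]] * s0[i] + wc[country[i]] * c0[i],
                  tau_meas)
    y1[i] ~ dnorm(b[i] + scale_i[i] * d[i] +
                  ws[country[i]] * s1[i] + wc[country[i]] * c1[i],
                  tau_meas)
  }
  for (k in 1:C) {
    B[k] ~ dnorm(baseline_loc, baseline_prec)
    ", dc_line, "
    ws[k] ~ dnorm(ws0, tau_season)
    wc[k] ~ dnorm(wc0, tau_season)
  }
  D ~ dnorm(effect_loc, effect_prec)
  ws0 ~ dnorm(0, season_prec)
  wc0 ~ dnorm(0, season_prec)
  ", sigma_m_line, "
  sigma_between ~ dnorm(0, sd_prec) T(0,)
  sigma_effect ~ dnorm(0, sd_prec) T(0,)
  sigma_country ~ dnorm(0, sd_prec) T(0,)
  sigma_season ~ dnorm(0, season_prec) T(0,)
  ", drift_line, "
  tau_meas <- pow(sigma_meas, -2)
  tau_between <- pow(sigma_between, -2)
  tau_effect <- pow(sigma_effect, -2)
  tau_country <- pow(sigma_country, -2)
  tau_season <- pow(sigma_season, -2)
}")
}

.core_params <- function(inputs, spec) {
  C <- inputs$n_countries
  c(sprintf("B[%d]", 1:C), sprintf("Dc[%d]", 1:C), "D",
    sprintf("ws[%d]", 1:C), sprintf("wc[%d]", 1:C), "ws0", "wc0",
    if (is.null(spec$sigma_meas_fixed)) "sigma_meas",
    "sigma_between", "sigma_effect", "sigma_country", "sigma_season",
    if (spec$estimate_drift) "drift")
}

## split-chain potential-scale-reduction and crude effective sample size,
## vectorized over the columns of per-chain draw matrices
.split_rhat <- function(chain_mats) {
  halves <- unlist(lapply(chain_mats, function(m) {
    h <- nrow(m) %/% 2
    list(m[seq_len(h), , drop = FALSE],
         m[(h + 1):(2 * h), , drop = FALSE])
  }), recursive = FALSE)
  n <- nrow(halves[[1]])
  means <- vapply(halves, colMeans, numeric(ncol(halves[[1]])))
  vars <- vapply(halves, function(m) apply(m, 2, stats::var),
                 numeric(ncol(halves[[1]])))
  if (is.null(dim(means))) { means <- t(means); vars <- t(vars) }
  W <- rowMeans(vars)
  B <- n * apply(means, 1, stats::var)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Fit the hierarchical adherence model
#'
#' The main fitting function. The observation model for subject i of
#' country c is
#' \deqn{y_{T0,i} \sim N(b_i + season_c(t_{0i}),\ \sigma_{meas})}
#' \deqn{y_{T1,i} \sim N(b_i + s_i d_i + season_c(t_{1i}),\ \sigma_{meas})}
#' where `b_i ~ N(B_c, sigma_between)` are latent subject baselines around
#' their country centre, `d_i ~ N(D_c, sigma_effect)` subject-level
#' intervention effects around country effects `D_c ~ N(D, sigma_country)`,
#' `s_i` is 1 for intervention subjects and the small participation drift
#' fraction for controls, and `season_c(t) = ws_c sin(2*pi*t) + wc_c
#' cos(2*pi*t)` is a country-level yearly oscillation whose weights are
#' pooled hierarchically around shared weights. Priors and sampler settings
#' come from [model_spec()].
#'
#' Sampling runs `n_repeats` independent seeded repeats of a multi-chain
#' Gibbs sampler (JAGS); the model is conditionally conjugate, so Gibbs
#' mixes well here. Draws are pooled across repeats for summaries, and
#' per-repeat means are kept as a stability diagnostic. Split-chain
#' potential-scale-reduction factors and effective sample sizes are
#' computed for the population-level parameters; the fit is flagged (with a
#' warning, never silently) when any scale-reduction factor exceeds 1.01.
#'
#' @param records Visit-records data frame (see [build_inputs()]), or an
#'   `"adherence_inputs"` object.
#' @param spec A [model_spec()].
#' @param seed Integer seed; all chain RNG seeds derive from it.
#' @param quiet Suppress JAGS progress output (default `TRUE`).
#' @return An object of class `"adherence_fit"`; see
#'   [summarize_posterior()], [correct_scores()], [variance_ratio()],
#'   [seasonality_estimates()] and the `print`, `summary`, `coef`, `plot`
#'   and `fitted` methods.
#' @export
fit_adherence <- function(records, spec = model_spec(), seed = 1L,
                          quiet = TRUE) {
  inputs <- if (inherits(records, "adherence_inputs")) records
            else build_inputs(records)
  if (!inherits(spec, "model_spec"))
    stop("'spec' must be a model_spec object", call. = FALSE)
  set.seed(as.integer(seed))
  rng_seeds <- sample.int(.Machine$integer.max - 1L,
                          spec$n_repeats * spec$chains)

  data <- list(
    N = inputs$n_subjects, C = inputs$n_countries,
    country = inputs$country_idx, intervention = inputs$intervention,
    y0 = inputs$y0, y1 = inputs$y1,
    s0 = sin(2 * pi * inputs$t0), c0 = cos(2 * pi * inputs$t0),
    s1 = sin(2 * pi * inputs$t1), c1 = cos(2 * pi * inputs$t1),
    baseline_loc = spec$baseline_center_loc,
    baseline_prec = spec$baseline_center_scale^-2,
    effect_loc = spec$effect_loc,
    effect_prec = spec$effect_scale^-2,
    sd_prec = spec$sd_prior_scale^-2,
    season_prec = spec$seasonal_weight_scale^-2,
    drift_loc = spec$control_drift)
  if (spec$estimate_drift) data$drift_prec <- spec$drift_prior_sd^-2
  if (spec$robust_effects) data$effect_df <- spec$effect_df
  if (!is.null(spec$sigma_meas_fixed))
    data$sigma_meas_fixed <- spec$sigma_meas_fixed

  model_str <- .jags_model_string(spec)
  core <- .core_params(inputs, spec)
  monitors <- unique(sub("\\[.*", "", core))

  t_start <- Sys.time()
  repeats <- vector("list", spec$n_repeats)
  subj_stats <- vector("list", spec$n_repeats)
  for (r in seq_len(spec$n_repeats)) {
    inits <- lapply(seq_len(spec$chains), function(ch)
      list(.RNG.name = "base::Mersenne-Twister",
           .RNG.seed = rng_seeds[(r - 1L) * spec$chains + ch]))
    jm <- rjags::jags.model(textConnection(model_str), data = data,
                            inits = inits, n.chains = spec$chains,
                            n.adapt = spec$adapt, quiet = quiet)
    if (spec$warmup > 0L)
      stats::update(jm, spec$warmup, progress.bar = "none")
    smp <- rjags::coda.samples(jm, c(monitors, "b", "d"),
                               n.iter = spec$draws,
                               progress.bar = "none")
    cmat <- lapply(smp, function(m) {
      mm <- as.matrix(m)
      ## JAGS drops the index on length-1 vector nodes (e.g. one country)
      cn <- colnames(mm)
      bare <- cn %in% c("B", "Dc", "ws", "wc")
      cn[bare] <- paste0(cn[bare], "[1]")
      colnames(mm) <- cn
      mm[, core, drop = FALSE]
    })
    ## per-subject posterior summaries; raw subject draws are not retained
    N <- inputs$n_subjects
    bi <- sprintf("b[%d]", seq_len(N))
    di <- sprintf("d[%d]", seq_len(N))
    scale_i <- ifelse(inputs$intervention == 1L, 1,
                      if (spec$estimate_drift) NA_real_
                      else spec$control_drift)
    ball <- do.call(rbind, lapply(smp, function(m)
      as.matrix(m)[, bi, drop = FALSE]))
    dall <- do.call(rbind, lapply(smp, function(m)
      as.matrix(m)[, di, drop = FALSE]))
    if (spec$estimate_drift) {
      drift_draws <- do.call(rbind, cmat)[, "drift"]
      ## scale = intervention + (1 - intervention) * drift, per draw
      scale_mat <- matrix(inputs$intervention, nrow(dall), N,
                          byrow = TRUE) +
        outer(drift_draws, 1 - inputs$intervention)
      t1corr <- ball + scale_mat * dall
    } else {
      t1corr <- ball + sweep(dall, 2L, scale_i, `*`)
    }
    subj_stats[[r]] <- list(
      b_mean = colMeans(ball), b_sd = apply(ball, 2, stats::sd),
      d_mean = colMeans(dall), d_sd = apply(dall, 2, stats::sd),
      t1_mean = colMeans(t1corr), t1_sd = apply(t1corr, 2, stats::sd))
    repeats[[r]] <- cmat
    rm(ball, dall, t1corr, smp)
  }
  runtime <- as.numeric(Sys.time() - t_start, units = "secs")

  ## diagnostics over population-level parameters, per repeat
  diag <- do.call(rbind, lapply(seq_len(spec$n_repeats), function(r) {
    cm <- repeats[[r]]
    rhat <- .split_rhat(cm)
    ess <- tryCatch({
      per_chain <- vapply(cm, function(m)
        coda::effectiveSize(coda::mcmc(m)), numeric(length(core)))
      if (is.null(dim(per_chain))) per_chain else rowSums(per_chain)
    }, error = function(e) rep(NA_real_, length(core)))
    data.frame(repeat_id = r, parameter = core, rhat = rhat, ess = ess,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  flagged <- any(diag$rhat > 1.01, na.rm = TRUE)
  if (flagged)
    warning("convergence flag: split-chain scale-reduction factor above ",
            "1.01 for ", sum(diag$rhat > 1.01, na.rm = TRUE),
            " parameter/repeat combination(s)", call. = FALSE)

  ## pooled subject summaries across repeats (means of means; SDs pooled
  ## as root-mean-square, adding the between-repeat spread of the means)
  pool_subject <- function(field_m, field_s) {
    mm <- vapply(subj_stats, `[[`, numeric(inputs$n_subjects), field_m)
    ss <- vapply(subj_stats, `[[`, numeric(inputs$n_subjects), field_s)
    if (is.null(dim(mm))) { mm <- matrix(mm, 1); ss <- matrix(ss, 1) }
    m <- rowMeans(mm)
    v <- rowMeans(ss^2) + apply(mm, 1, stats::var) *
      (spec$n_repeats > 1)
    list(mean = m, sd = sqrt(v))
  }
  b_pool <- pool_subject("b_mean", "b_sd")
  d_pool <- pool_subject("d_mean", "d_sd")
  t1_pool <- pool_subject("t1_mean", "t1_sd")

  structure(list(
    repeats = repeats, core_params = core, inputs = inputs, spec = spec,
    seed = as.integer(seed), rng_seeds = rng_seeds,
    subject = data.frame(
      subject_id = inputs$subject_id,
      country = inputs$country_levels[inputs$country_idx],
      arm = inputs$arm,
      b_mean = b_pool$mean, b_sd = b_pool$sd,
      d_mean = d_pool$mean, d_sd = d_pool$sd,
      t1_mean = t1_pool$mean, t1_sd = t1_pool$sd,
      stringsAsFactors = FALSE),
    diagnostics = diag, flagged = flagged, runtime = runtime),
    class = "adherence_fit")
}

#' Pooled posterior draws of the population-level parameters
#'
#' @param fit An `"adherence_fit"`.
#' @return Matrix of draws (rows: pooled draws across repeats and chains;
#'   columns: population-level parameters).
#' @export
pooled_draws <- function(fit) {
  stopifnot(inherits(fit, "adherence_fit"))
  do.call(rbind, lapply(fit$repeats, function(cm) do.call(rbind, cm)))
}
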