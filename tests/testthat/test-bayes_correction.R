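test_that("build_inputs validates and indexes a two-visit table", {
  rec <- data.frame(
    subject_id = rep(c("a", "b"), each = 2),
    country = rep(c("X", "Y"), each = 2),
    arm = rep(c("control", "intervention"), each = 2),
    visit = rep(c("T0", "T1"), 2),
    date_fraction = c(0, 0.5, 0.25, 0.75),
    observed_score = c(80, 81, 90, 110))
  inp <- build_inputs(rec)
  expect_s3_class(inp, "adherence_inputs")
  expect_equal(inp$n_subjects, 2L)
  expect_equal(length(c(inp$y0, inp$y1)), 4L)
  expect_equal(inp$country_levels[inp$country_idx],
               c("X", "Y"))
  expect_equal(inp$intervention, c(0L, 1L))

  expect_error(build_inputs(rec[-2, ]), "a")             # missing T1
  expect_error(build_inputs(rbind(rec, rec[1, ])), "duplicated")
  bad <- rec; bad$arm[1:2] <- "placebo"
  expect_error(build_inputs(bad), "placebo")
})

test_that("calendar dates map to year fractions on [0, 1)", {
  expect_equal(date_fraction(as.Date("2013-01-01")), 0)
  # day 183 of a non-leap year (2 July)
  expect_equal(date_fraction(as.Date("2013-07-02")), 182 / 365.25)
  expect_equal(round(date_fraction(as.Date("2013-07-02")), 3), 0.498)
})

test_that("highest-density intervals match their sample oracles", {
  expect_equal(hdi(rep(3.2, 500), 0.5), c(3.2, 3.2))
  set.seed(8)
  z <- rnorm(1e5)
  h95 <- hdi(z, 0.95)
  expect_lt(abs(h95[1] - qnorm(0.025)), 0.05)
  expect_lt(abs(h95[2] - qnorm(0.975)), 0.05)
  # nesting: the 50% interval sits inside the 95% interval
  g <- rgamma(5e4, shape = 2)
  h50 <- hdi(g, 0.5); h95 <- hdi(g, 0.95)
  expect_gte(h50[1], h95[1])
  expect_lte(h50[2], h95[2])
  expect_true(mean(g) >= h95[1] && mean(g) <= h95[2])
})

test_that("with negligible measurement noise the fit returns the data", {
  cfg <- cohort_config(countries = flat_countries(20), sigma_meas = 0,
                       sigma_effect = 0)
  co <- generate_cohort(cfg, seed = 15)
  fit <- suppressWarnings(
    fit_adherence(co$records, fast_spec(sigma_meas_fixed = 0.01),
                  seed = 15))
  # posterior subject baselines reproduce the observed baseline scores
  # minus the (weakly identified) fitted seasonal term: the likelihood
  # pins each subject exactly, draw by draw
  cs <- correct_scores(fit)
  draws <- pooled_draws(fit)
  lev <- fit$inputs$country_levels
  ws <- colMeans(draws[, sprintf("ws[%d]", seq_along(lev)), drop = FALSE])
  wc <- colMeans(draws[, sprintf("wc[%d]", seq_along(lev)), drop = FALSE])
  k <- fit$inputs$country_idx
  s0 <- seasonal_value(ws[k], wc[k], fit$inputs$t0)
  s1 <- seasonal_value(ws[k], wc[k], fit$inputs$t1)
  expect_lt(max(abs(cs$corrected_t0 - (cs$raw_t0 - s0))), 0.1)
  expect_lt(max(abs(cs$corrected_t1 - (cs$raw_t1 - s1))), 0.1)
})

test_that("small-cohort fit recovers generating parameters loosely", {
  co <- generate_cohort(cohort_config(countries = scaled_countries(80)),
                        seed = 23)
  fit <- fit_adherence(co$records, fast_spec(), seed = 23)
  cf <- coef(fit)
  nonoutlier <- setdiff(rownames(cf), "FR")
  expect_lt(abs(mean(cf[nonoutlier, "effect"]) - 20), 4)
  expect_lt(abs(cf["FR", "effect"] - 38), 8)
  vr <- variance_ratio(fit)
  expect_lt(abs(vr$median - 1.03), 0.3)
  expect_lt(vr$iqr[1], vr$median)
  expect_gt(vr$iqr[2], vr$median)
  # summaries are internally coherent
  ps <- summarize_posterior(fit)
  p <- ps$parameters
  expect_true(all(p$hdi50_lower >= p$hdi95_lower - 1e-9))
  expect_true(all(p$hdi50_upper <= p$hdi95_upper + 1e-9))
  expect_true(all(p$mean >= p$hdi95_lower & p$mean <= p$hdi95_upper))
})

test_that("seasonal peak convention: pure positive cosine peaks on 1 Jan", {
  # low-noise design so the check exercises the angle convention, not the
  # sampling variability of the weights
  countries <- list(country_spec("A", 300, 80, 20,
                                 seasonal_weight_sin = 0,
                                 seasonal_weight_cos = 5))
  cfg <- cohort_config(countries = countries, sigma_meas = 6,
                       sigma_between = 6)
  co <- generate_cohort(cfg, seed = 33)
  fit <- suppressWarnings(fit_adherence(co$records, fast_spec(),
                                        seed = 33))
  se <- seasonality_estimates(fit)
  dist_from_jan1 <- min(se$peak_fraction, 1 - se$peak_fraction)
  expect_lt(dist_from_jan1, 0.08)
  expect_lt(abs(se$amplitude - 5), 1.5)
})

test_that("corrected scores shrink toward the country trend", {
  co <- generate_cohort(cohort_config(countries = scaled_countries(60)),
                        seed = 41)
  fit <- fit_adherence(co$records, fast_spec(), seed = 41)
  cs <- correct_scores(fit)
  ctrl <- cs$arm == "control"

  # controls converge toward the identity line
  expect_lt(mean(abs(cs$corrected_t1[ctrl] - cs$corrected_t0[ctrl])),
            mean(abs(cs$raw_t1[ctrl] - cs$raw_t0[ctrl])))

  # intervention subjects converge toward identity + country effect
  cf <- coef(fit)
  eff <- cf[cs$country, "effect"]
  intv <- !ctrl
  expect_lt(mean(abs(cs$corrected_t1[intv] - cs$corrected_t0[intv] -
                       eff[intv])),
            mean(abs(cs$raw_t1[intv] - cs$raw_t0[intv] - eff[intv])))

  # partial pooling: every corrected baseline lies inside the hull of the
  # country centre and the subject's seasonally/effect-adjusted scores
  draws <- pooled_draws(fit)
  lev <- fit$inputs$country_levels
  ws <- colMeans(draws[, sprintf("ws[%d]", seq_along(lev)), drop = FALSE])
  wc <- colMeans(draws[, sprintf("wc[%d]", seq_along(lev)), drop = FALSE])
  k <- fit$inputs$country_idx
  s0 <- seasonal_value(ws[k], wc[k], fit$inputs$t0)
  s1 <- seasonal_value(ws[k], wc[k], fit$inputs$t1)
  scale_i <- ifelse(fit$inputs$intervention == 1L, 1,
                    fit$spec$control_drift)
  anchors <- cbind(cf[cs$country, "baseline"],
                   cs$raw_t0 - s0,
                   cs$raw_t1 - s1 - scale_i * fit$subject$d_mean)
  lo <- apply(anchors, 1, min)
  hi <- apply(anchors, 1, max)
  expect_true(all(cs$corrected_t0 >= lo - 0.5 &
                    cs$corrected_t0 <= hi + 0.5))
})

test_that("doubling the generating measurement SD doubles the ratio", {
  base <- cohort_config(countries = flat_countries(60, n_countries = 5),
                        sigma_meas = 8)
  doubled <- cohort_config(countries = flat_countries(60, n_countries = 5),
                           sigma_meas = 16)
  f1 <- fit_adherence(generate_cohort(base, seed = 51)$records,
                      fast_spec(), seed = 51)
  f2 <- fit_adherence(generate_cohort(doubled, seed = 51)$records,
                      fast_spec(), seed = 52)
  m1 <- variance_ratio(f1)$median
  m2 <- variance_ratio(f2)$median
  expect_lt(abs(m2 / m1 - 2), 0.6)
})

test_that("posterior summary refuses too few draws", {
  co <- generate_cohort(cohort_config(countries = flat_countries(15)),
                        seed = 61)
  fit <- fit_adherence(co$records,
                       model_spec(chains = 1L, adapt = 150L, warmup = 50L,
                                  draws = 50L, n_repeats = 1L),
                       seed = 61)
  expect_error(summarize_posterior(fit), "100")
})

test_that("null-model inversion concords with the full-model ratio", {
  # the package's own cross-check: inverting the intervention arm's
  # observed difference-baseline correlation through the null model must
  # land on the same within/between ratio the hierarchical model recovers
  co <- generate_cohort(cohort_config(countries = scaled_countries(150)),
                        seed = 71)
  interv <- co$records[co$records$arm == "intervention", ]
  tab <- regression_to_mean_table(interv)
  curve <- simulate_null(
    null_model_config(n_subjects = tab$n, reps = 50,
                      lambda_grid = seq(0, 3, 0.2)),
    seed = 72)
  est <- invert_curve(curve, tab$r_diff_t0)
  fit <- suppressWarnings(
    fit_adherence(co$records,
                  model_spec(chains = 2L, adapt = 300L, warmup = 300L,
                             draws = 500L, n_repeats = 1L),
                  seed = 73))
  vr <- variance_ratio(fit)
  # overlapping interquartile ranges
  expect_lte(max(est$iqr[1], vr$iqr[1]), min(est$iqr[2], vr$iqr[2]))
})
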