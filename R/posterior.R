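#' Highest-density interval of a sample
#'
#' The contiguous interval of minimal width containing the stated posterior
#' mass, found by sliding a window over the sorted draws. Multimodal
#' posteriors are still reported as a single interval (documented
#' limitation of the contiguous definition).
#'
#' @param x Numeric draws.
#' @param mass Probability mass, in (0, 1).
#' @return Length-2 numeric `c(lower, upper)`.
#' @export
hdi <- function(x, mass = 0.95) {
  stopifnot(is.numeric(x), length(x) > 1L, mass > 0, mass < 1)
  x <- sort(x[is.finite(x)])
  n <- length(x)
  k <- max(1L, ceiling(mass * n))
  if (k >= n) return(c(x[1], x[n]))
  widths <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(widths)[1]   # ties: leftmost interval
  c(x[i], x[i + k])
}

#' Summarise the posterior of a fitted adherence model
#'
#' Produces the population-level parameter table (posterior means, 50% and
#' 95% highest-density intervals from the pooled draws, per-repeat means,
#' and convergence diagnostics), the variance components with the
#' within/between ratio, and the per-country seasonality estimates.
#'
#' @param fit An `"adherence_fit"` from [fit_adherence()].
#' @return An object of class `"posterior_summary"`: list with
#'   `parameters` (data frame), `variance_ratio` (see [variance_ratio()]),
#'   `seasonality` (see [seasonality_estimates()]), `flagged`.
#' @export
summarize_posterior <- function(fit) {
  stopifnot(inherits(fit, "adherence_fit"))
  draws <- pooled_draws(fit)
  if (nrow(draws) < 100L)
    stop("too few pooled draws (< 100) to summarise", call. = FALSE)
  rep_means <- vapply(fit$repeats, function(cm)
    colMeans(do.call(rbind, cm)), numeric(ncol(draws)))
  if (is.null(dim(rep_means)))
    rep_means <- matrix(rep_means, nrow = 1,
                        dimnames = list(colnames(draws), NULL))
  h50 <- apply(draws, 2, hdi, mass = 0.50)
  h95 <- apply(draws, 2, hdi, mass = 0.95)
  dg <- stats::aggregate(cbind(rhat, ess) ~ parameter,
                         data = fit$diagnostics,
                         FUN = function(v) max(v, na.rm = TRUE))
  dg$ess <- stats::aggregate(ess ~ parameter, data = fit$diagnostics,
                             FUN = sum)$ess
  m <- match(colnames(draws), dg$parameter)
  params <- data.frame(
    parameter = colnames(draws),
    mean = colMeans(draws),
    hdi50_lower = h50[1, ], hdi50_upper = h50[2, ],
    hdi95_lower = h95[1, ], hdi95_upper = h95[2, ],
    rhat_max = dg$rhat[m], ess_total = dg$ess[m],
    stringsAsFactors = FALSE, row.names = NULL)
  colnames(rep_means) <- sprintf("repeat%d_mean", seq_len(ncol(rep_means)))
  params <- cbind(params, rep_means[match(params$parameter,
                                          rownames(rep_means)), ,
                                    drop = FALSE])
  rownames(params) <- NULL
  structure(list(parameters = params,
                 variance_ratio = variance_ratio(fit),
                 seasonality = seasonality_estimates(fit),
                 country_levels = fit$inputs$country_levels,
                 flagged = fit$flagged),
            class = "posterior_summary")
}

#' Posterior of the within/between variability ratio
#'
#' Computes the draw-wise ratio of the measurement (within-subject) SD to
#' the between-subject baseline SD and summarises it by the posterior
#' median, interquartile range and central 95% interval — the quantity the
#' regression-to-the-mean null model estimates from the observed
#' difference-baseline correlation, here recovered inside the full model.
#'
#' @param fit An `"adherence_fit"`.
#' @return An object of class `"variance_ratio"`: list with `median`,
#'   `iqr`, `interval95`, `draws`, and the component summaries
#'   `sigma_meas`, `sigma_between` (posterior means).
#' @export
variance_ratio <- function(fit) {
  stopifnot(inherits(fit, "adherence_fit"))
  draws <- pooled_draws(fit)
  s_m <- if ("sigma_meas" %in% colnames(draws)) draws[, "sigma_meas"]
         else rep(fit$spec$sigma_meas_fixed, nrow(draws))
  s_b <- draws[, "sigma_between"]
  lam <- s_m / s_b
  structure(list(
    median = stats::median(lam),
    iqr = unname(stats::quantile(lam, c(0.25, 0.75))),
    interval95 = unname(stats::quantile(lam, c(0.025, 0.975))),
    draws = lam,
    sigma_meas = mean(s_m), sigma_between = mean(s_b)),
    class = "variance_ratio")
}

#' @export
print.variance_ratio <- function(x, ...) {
  cat(sprintf(
    "Within/between ratio: median %.3f, IQR [%.3f, %.3f], 95%% [%.3f, %.3f]\n",
    x$median, x$iqr[1], x$iqr[2], x$interval95[1], x$interval95[2]))
  cat(sprintf("  sigma_meas %.2f, sigma_between %.2f (posterior means)\n",
              x$sigma_meas, x$sigma_between))
  invisible(x)
}

#' Per-country seasonality estimates
#'
#' Summarises the posterior of each country's yearly oscillation: the two
#' weights, the amplitude `sqrt(ws^2 + wc^2)` (the excursion above and
#' below the yearly average), the peak-to-trough difference (twice the
#' amplitude; the difference between the seasonal extremes), and the year
#' fraction of the peak, `atan2(ws, wc) / (2*pi)` mod 1 (so a pure cosine
#' with positive weight peaks at 0, i.e. 1 January). The peak fraction is
#' summarised by the circular mean of the draw-wise peak positions.
#'
#' Because the amplitude is the norm of two noisy weights it is positive
#' by construction and biased upward when the weights are uncertain: even a
#' country with no true seasonality shows a posterior amplitude around the
#' weights' posterior SD. `amplitude_of_mean` (the norm of the posterior
#' mean weight vector, which shrinkage pulls toward zero) together with the
#' weight SDs is the better detectability check; `amplitude` (the posterior
#' mean of the draw-wise norm) is the summary to read when seasonality is
#' clearly present.
#'
#' @param fit An `"adherence_fit"`.
#' @return Data frame, one row per country: posterior mean weights and
#'   their SDs, `amplitude` (posterior mean of the draw-wise norm),
#'   `amplitude_median`, `amplitude_of_mean`, `amplitude_hdi50_*`,
#'   `amplitude_hdi95_*`, `peak_to_trough`, `peak_fraction`.
#' @export
seasonality_estimates <- function(fit) {
  stopifnot(inherits(fit, "adherence_fit"))
  draws <- pooled_draws(fit)
  levels <- fit$inputs$country_levels
  out <- lapply(seq_along(levels), function(k) {
    ws <- draws[, sprintf("ws[%d]", k)]
    wc <- draws[, sprintf("wc[%d]", k)]
    amp <- sqrt(ws^2 + wc^2)
    h50 <- hdi(amp, 0.50); h95 <- hdi(amp, 0.95)
    peaks <- (atan2(ws, wc) / (2 * pi)) %% 1
    ## circular mean of peak year fractions
    pk <- (atan2(mean(sin(2 * pi * peaks)),
                 mean(cos(2 * pi * peaks))) / (2 * pi)) %% 1
    data.frame(country = levels[k],
               weight_sin = mean(ws), weight_cos = mean(wc),
               weight_sin_sd = stats::sd(ws), weight_cos_sd = stats::sd(wc),
               amplitude = mean(amp),
               amplitude_median = stats::median(amp),
               amplitude_of_mean = sqrt(mean(ws)^2 + mean(wc)^2),
               amplitude_hdi50_lower = h50[1],
               amplitude_hdi50_upper = h50[2],
               amplitude_hdi95_lower = h95[1],
               amplitude_hdi95_upper = h95[2],
               peak_to_trough = 2 * mean(amp),
               peak_fraction = pk,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Shrinkage-corrected per-subject adherence scores
#'
#' The central output of the model: for each subject, the posterior mean of
#' the latent baseline (`corrected_t0`) and of the baseline plus the
#' arm-scaled subject effect (`corrected_t1`), with posterior SDs. The
#' seasonal term is excluded from both corrected values, so they estimate
#' the subject's yearly-average adherence; partial pooling pulls noisy
#' extreme measurements toward the country trend in proportion to the
#' measurement uncertainty.
#'
#' @param fit An `"adherence_fit"`.
#' @return Data frame with `subject_id`, `country`, `arm`, raw scores
#'   (`raw_t0`, `raw_t1`), `corrected_t0`, `corrected_t0_sd`,
#'   `corrected_t1`, `corrected_t1_sd`.
#' @export
correct_scores <- function(fit) {
  stopifnot(inherits(fit, "adherence_fit"))
  s <- fit$subject
  data.frame(subject_id = s$subject_id, country = s$country, arm = s$arm,
             raw_t0 = fit$inputs$y0, raw_t1 = fit$inputs$y1,
             corrected_t0 = s$b_mean, corrected_t0_sd = s$b_sd,
             corrected_t1 = s$t1_mean, corrected_t1_sd = s$t1_sd,
             stringsAsFactors = FALSE)
}

#' @export
print.adherence_fit <- function(x, ...) {
  cat("Hierarchical adherence model fit\n")
  cat(sprintf("  %d subjects, %d countries; %d repeat(s) x %d chain(s) x %d draws\n",
              x$inputs$n_subjects, x$inputs$n_countries,
              x$spec$n_repeats, x$spec$chains, x$spec$draws))
  cat(sprintf("  runtime %.1f s; max split-Rhat %.3f%s\n", x$runtime,
              max(x$diagnostics$rhat, na.rm = TRUE),
              if (x$flagged) " [FLAGGED: check convergence]" else ""))
  vr <- variance_ratio(x)
  cat(sprintf("  within/between ratio: median %.3f, IQR [%.3f, %.3f]\n",
              vr$median, vr$iqr[1], vr$iqr[2]))
  invisible(x)
}

#' @export
summary.adherence_fit <- function(object, ...) summarize_posterior(object)

#' @export
print.posterior_summary <- function(x, ...) {
  cat("Posterior summary (pooled draws)\n")
  core <- x$parameters[!grepl("^(ws|wc)", x$parameters$parameter),
                       c("parameter", "mean", "hdi50_lower", "hdi50_upper",
                         "hdi95_lower", "hdi95_upper", "rhat_max")]
  core[-1] <- lapply(core[-1], round, digits = 3)
  print(core, row.names = FALSE)
  cat("\nSeasonality (per country):\n")
  ss <- x$seasonality[, c("country", "amplitude", "peak_to_trough",
                          "peak_fraction")]
  ss[-1] <- lapply(ss[-1], round, digits = 3)
  print(ss, row.names = FALSE)
  cat("\n")
  print(x$variance_ratio)
  if (isTRUE(x$flagged))
    cat("NOTE: convergence flagged for some parameters; inspect diagnostics\n")
  invisible(x)
}

#' Country-level coefficients of a fitted adherence model
#'
#' @param object An `"adherence_fit"`.
#' @param ... Unused.
#' @return Matrix with one row per country and columns `baseline`
#'   (posterior mean country baseline centre) and `effect` (posterior mean
#'   country intervention effect).
#' @export
coef.adherence_fit <- function(object, ...) {
  draws <- pooled_draws(object)
  C <- object$inputs$n_countries
  out <- cbind(
    baseline = colMeans(draws[, sprintf("B[%d]", 1:C), drop = FALSE]),
    effect = colMeans(draws[, sprintf("Dc[%d]", 1:C), drop = FALSE]))
  rownames(out) <- object$inputs$country_levels
  out
}

#' @export
fitted.adherence_fit <- function(object, ...) correct_scores(object)

#' Forest-style plot of country baselines and effects
#'
#' @param x An `"adherence_fit"`.
#' @param which `"baseline"` or `"effect"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.adherence_fit <- function(x, which = c("baseline", "effect"), ...) {
  which <- match.arg(which)
  draws <- pooled_draws(x)
  C <- x$inputs$n_countries
  pars <- sprintf(if (which == "baseline") "B[%d]" else "Dc[%d]", 1:C)
  m <- colMeans(draws[, pars, drop = FALSE])
  h50 <- apply(draws[, pars, drop = FALSE], 2, hdi, mass = 0.50)
  h95 <- apply(draws[, pars, drop = FALSE], 2, hdi, mass = 0.95)
  ylim <- range(h95)
  graphics::plot(seq_len(C), m, pch = 16, ylim = ylim, xaxt = "n",
                 xlab = "country",
                 ylab = if (which == "baseline")
                   "baseline index (points)" else
                   "intervention effect (points)", ...)
  graphics::axis(1, at = seq_len(C), labels = x$inputs$country_levels)
  graphics::segments(seq_len(C), h95[1, ], seq_len(C), h95[2, ], lwd = 1)
  graphics::segments(seq_len(C), h50[1, ], seq_len(C), h50[2, ], lwd = 3)
  invisible(x)
}
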