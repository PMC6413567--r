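#' Closed-form difference-baseline correlation under the null model
#'
#' For the idealised measurement model with standard-normal true baselines
#' `B`, optional standard-normal between-visit change `C`, and i.i.d.
#' measurement noise `e0, e1 ~ N(0, lambda)` added to both visits
#' (`T0 = B + e0`, `T1 = B + C + e1`), the Pearson correlation between the
#' baseline measurement and the observed change `T1 - T0` is
#' \deqn{r(\lambda) = \frac{-\lambda^2}{\sqrt{(1+\lambda^2)(1+2\lambda^2)}}}
#' with the change term, and
#' \deqn{r(\lambda) = \frac{-\lambda}{\sqrt{2(1+\lambda^2)}}}
#' without it. Both are 0 at `lambda = 0` and approach `-1/sqrt(2)` as
#' `lambda` grows: pure regression to the mean never pushes the correlation
#' below about -0.707.
#'
#' @param lambda Within/between variability ratio(s), `>= 0`.
#' @param include_change Include the between-visit change term (default
#'   `TRUE`, the canonical variant).
#' @return Expected Pearson correlation(s), in `[-1/sqrt(2), 0]`.
#' @examples
#' expected_correlation(1)        # -1/sqrt(6)
#' expected_correlation(1e6)      # ~ -0.7071
#' @export
expected_correlation <- function(lambda, include_change = TRUE) {
  if (any(!is.finite(lambda)) || any(lambda < 0))
    stop("'lambda' must be finite and >= 0", call. = FALSE)
  if (include_change)
    -lambda^2 / sqrt((1 + lambda^2) * (1 + 2 * lambda^2))
  else
    -lambda / sqrt(2 * (1 + lambda^2))
}

#' Configuration for the regression-to-the-mean null simulation
#'
#' @param n_subjects Subjects per simulated study (default 1,133, the size
#'   of the motivating cohort).
#' @param lambda_grid Grid of within/between ratios to simulate.
#' @param reps Independent replicate studies per grid point.
#' @param include_change Include the `N(0,1)` between-visit change term.
#' @param seed Optional integer seed stored with the configuration.
#' @return An object of class `"null_model_config"`.
#' @export
null_model_config <- function(n_subjects = 1133L,
                              lambda_grid = seq(0, 3, by = 0.2),
                              reps = 50L,
                              include_change = TRUE,
                              seed = NULL) {
  n_subjects <- as.integer(n_subjects)
  reps <- as.integer(reps)
  if (is.na(n_subjects) || n_subjects < 2L)
    stop("'n_subjects' must be >= 2", call. = FALSE)
  if (any(!is.finite(lambda_grid)) || any(lambda_grid < 0))
    stop("'lambda_grid' values must be finite and >= 0", call. = FALSE)
  if (is.na(reps) || reps < 1L)
    stop("'reps' must be >= 1", call. = FALSE)
  structure(list(n_subjects = n_subjects,
                 lambda_grid = as.numeric(lambda_grid), reps = reps,
                 include_change = isTRUE(include_change), seed = seed),
            class = "null_model_config")
}

#' Simulate the regression-to-the-mean null model
#'
#' For each ratio in `lambda_grid` and each replicate, draws `n_subjects`
#' idealised paired measurements (`B ~ N(0,1)`; optional change `C ~
#' N(0,1)`; noise `e0, e1 ~ N(0, lambda)`; `T0 = B + e0`, `T1 = B + C +
#' e1`) and records the Pearson correlation between `T0` and `T1 - T0`.
#'
#' @param config A [null_model_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return An object of class `"correlation_curve"`: a list with `lambda`,
#'   `mean_r`, `mc_se` (Monte-Carlo standard error of the mean), the
#'   `reps x length(lambda)` matrix `rep_r` of per-replicate correlations,
#'   and the simulation settings.
#' @seealso [expected_correlation()] for the closed form, [invert_curve()]
#'   for mapping an observed correlation back to the ratio.
#' @export
simulate_null <- function(config, seed = config$seed) {
  if (!inherits(config, "null_model_config"))
    stop("'config' must be a null_model_config object", call. = FALSE)
  if (is.null(seed))
    stop("a seed is required for reproducible simulation", call. = FALSE)
  set.seed(as.integer(seed))
  n <- config$n_subjects
  rep_r <- matrix(NA_real_, config$reps, length(config$lambda_grid))
  for (j in seq_along(config$lambda_grid)) {
    lam <- config$lambda_grid[j]
    for (k in seq_len(config$reps)) {
      B <- stats::rnorm(n)
      C <- if (config$include_change) stats::rnorm(n) else 0
      t0 <- B + stats::rnorm(n, 0, lam)
      t1 <- B + C + stats::rnorm(n, 0, lam)
      d <- t1 - t0
      ## constant difference (lambda = 0 without the change term): the
      ## correlation is 0 in the noise-free limit
      rep_r[k, j] <- if (stats::sd(d) == 0) 0 else stats::cor(t0, d)
    }
  }
  mean_r <- colMeans(rep_r)
  mc_se <- if (config$reps > 1L) {
    apply(rep_r, 2, stats::sd) / sqrt(config$reps)
  } else {
    ## single replicate: large-sample SE of a Pearson correlation
    (1 - mean_r^2) / sqrt(n - 1)
  }
  structure(list(lambda = config$lambda_grid, mean_r = mean_r,
                 mc_se = mc_se, rep_r = rep_r,
                 n_subjects = n, reps = config$reps,
                 include_change = config$include_change,
                 seed = as.integer(seed)),
            class = "correlation_curve")
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat("Regression-to-the-mean correlation curve\n")
  cat(sprintf("  n = %d subjects, %d rep(s)/point, change term %s\n",
              x$n_subjects, x$reps,
              if (x$include_change) "included" else "excluded"))
  print(data.frame(lambda = x$lambda, mean_r = round(x$mean_r, 4),
                   mc_se = signif(x$mc_se, 3)), row.names = FALSE)
  invisible(x)
}

#' @export
plot.correlation_curve <- function(x, ...) {
  graphics::plot(x$lambda, x$mean_r, type = "b", pch = 16,
                 xlab = expression(lambda ~ "(within/between ratio)"),
                 ylab = "corr(T0, T1 - T0)", ...)
  graphics::arrows(x$lambda, x$mean_r - 2 * x$mc_se,
                   x$lambda, x$mean_r + 2 * x$mc_se,
                   angle = 90, code = 3, length = 0.03)
  graphics::abline(h = -1 / sqrt(2), lty = 3)
  invisible(x)
}

## monotone (non-decreasing in |r|) rearrangement of a simulated curve,
## then linear interpolation of lambda at the observed correlation.
## Ties resolved toward the smaller lambda.
.invert_one <- function(lambda, r, observed_r) {
  iso <- stats::isoreg(lambda, -r)   # enforce |r| non-decreasing in lambda
  rr <- -iso$yf
  ok <- !duplicated(rr)              # keep first (smallest lambda) per value
  rr <- rr[ok]; ll <- lambda[ok]
  if (observed_r >= rr[1]) return(ll[1])
  if (observed_r <= rr[length(rr)]) return(ll[length(ll)])
  stats::approx(rr, ll, xout = observed_r, ties = "min")$y
}

#' Invert an observed difference-baseline correlation into a ratio estimate
#'
#' Maps an observed Pearson correlation between baseline and change back to
#' the within/between variability ratio using a simulated
#' [correlation curve][simulate_null]. The point estimate interpolates the
#' monotone-rearranged mean curve; the interquartile range comes from
#' inverting each per-replicate curve realisation, which propagates the
#' Monte-Carlo uncertainty of a study of that size.
#'
#' @param curve A `"correlation_curve"` from [simulate_null()].
#' @param observed_r Observed correlation, in `(-1/sqrt(2), 0]`. Values at
#'   or below the `-1/sqrt(2)` asymptote are unattainable under the null
#'   model and raise an error.
#' @return An object of class `"lambda_estimate"`: list with `lambda_hat`,
#'   `iqr` (length 2), `per_rep_lambda`, `observed_r`, and `ratio_gt_1`
#'   (`TRUE` when the IQR lower bound exceeds 1).
#' @export
invert_curve <- function(curve, observed_r) {
  if (!inherits(curve, "correlation_curve"))
    stop("'curve' must be a correlation_curve object", call. = FALSE)
  stopifnot(length(observed_r) == 1L, is.finite(observed_r))
  if (observed_r > 0)
    stop("'observed_r' must be <= 0 under the null model", call. = FALSE)
  if (observed_r <= -1 / sqrt(2))
    stop("'observed_r' at or below -1/sqrt(2) is unattainable: ",
         "no ratio produces a correlation that negative", call. = FALSE)
  lambda_hat <- .invert_one(curve$lambda, curve$mean_r, observed_r)
  per_rep <- apply(curve$rep_r, 1, .invert_one,
                   lambda = curve$lambda, observed_r = observed_r)
  iqr <- unname(stats::quantile(per_rep, c(0.25, 0.75), type = 7))
  structure(list(lambda_hat = lambda_hat, iqr = iqr,
                 per_rep_lambda = per_rep, observed_r = observed_r,
                 ratio_gt_1 = iqr[1] > 1),
            class = "lambda_estimate")
}

#' @export
print.lambda_estimate <- function(x, ...) {
  cat(sprintf(
    "Ratio estimate from observed r = %.3f: lambda = %.3f, IQR [%.3f, %.3f]\n",
    x$observed_r, x$lambda_hat, x$iqr[1], x$iqr[2]))
  if (isTRUE(x$ratio_gt_1))
    cat("  within-subject variability exceeds between-subject (ratio > 1)\n")
  invisible(x)
}

#' Per-arm regression-to-the-mean summary of a two-visit cohort
#'
#' For each arm, computes the mean and standard deviation of the observed
#' per-subject change (`T1 - T0`) and the Pearson correlation between the
#' change and the baseline score. A clearly negative correlation is the
#' signature of regression to the mean: measurement noise enters the
#' baseline and its negative enters the change.
#'
#' @param records Visit-records data frame with columns `subject_id`, `arm`,
#'   `visit` (`"T0"`/`"T1"`) and `observed_score`; every subject must have
#'   exactly one record per visit.
#' @return Data frame with one row per arm: `arm`, `n`, `mean_difference`,
#'   `sd_difference`, `r_diff_t0` (`NA` when the change is constant).
#' @export
regression_to_mean_table <- function(records) {
  req <- c("subject_id", "arm", "visit", "observed_score")
  if (!all(req %in% names(records)))
    stop("'records' must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  wide <- .pair_visits(records)
  out <- lapply(split(wide, wide$arm), function(d) {
    diff <- d$t1 - d$t0
    r <- if (stats::sd(diff) == 0 || stats::sd(d$t0) == 0) NA_real_
         else stats::cor(d$t0, diff)
    data.frame(arm = d$arm[1], n = nrow(d),
               mean_difference = mean(diff),
               sd_difference = stats::sd(diff),
               r_diff_t0 = r, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

## reshape visit records to one row per subject (t0, t1); errors list the
## offending subjects
.pair_visits <- function(records) {
  if (!all(records$visit %in% c("T0", "T1")))
    stop("'visit' must be 'T0' or 'T1'", call. = FALSE)
  key <- paste(records$subject_id, records$visit)
  if (anyDuplicated(key)) {
    dup <- unique(records$subject_id[duplicated(key)])
    stop("duplicated visit for subject(s): ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  t0 <- records[records$visit == "T0", ]
  t1 <- records[records$visit == "T1", ]
  missing <- union(setdiff(t0$subject_id, t1$subject_id),
                   setdiff(t1$subject_id, t0$subject_id))
  if (length(missing))
    stop("subject(s) with only one visit: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  m <- match(t0$subject_id, t1$subject_id)
  data.frame(subject_id = t0$subject_id, arm = t0$arm,
             country = if ("country" %in% names(t0)) t0$country else NA,
             t0 = t0$observed_score, t1 = t1$observed_score[m],
             t0_fraction = if ("date_fraction" %in% names(t0))
               t0$date_fraction else NA_real_,
             t1_fraction = if ("date_fraction" %in% names(t1))
               t1$date_fraction[m] else NA_real_,
             stringsAsFactors = FALSE)
}
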