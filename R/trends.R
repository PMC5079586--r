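#' Binomial GLM trend of an indicator proportion over years
#'
#' Logistic regression of per-year success counts (fish in an indicator
#' category) on calendar year, with the year covariate centred internally
#' for numerical conditioning (the slope is invariant to centring and is
#' reported per calendar year). Significance is the likelihood-ratio
#' chi-square against the intercept-only model, on 1 degree of freedom.
#'
#' @param successes Integer count per year of fish in the category.
#' @param totals Integer fish sampled per year (\code{totals >= successes}).
#' @param years Calendar years (at least 3).
#' @return Object of class \code{"binomial_trend_fit"}: \code{slope}
#'   (logit units per year), \code{intercept} (logit at the mean year),
#'   \code{lr_chisq}, \code{p_value}, \code{n_years}, \code{separation}
#'   (flag for quasi-complete separation).
#' @examples
#' fit_binomial_trend(c(20, 15, 10, 5), c(100, 100, 100, 100), 2001:2004)
#' @export
fit_binomial_trend <- function(successes, totals, years) {
  stopifnot(length(successes) == length(totals),
            length(totals) == length(years),
            all(totals >= successes), all(successes >= 0))
  if (length(unique(years)) < 3L) stop("need at least 3 years")
  yc <- years - mean(years)
  fit <- suppressWarnings(
    stats::glm(cbind(successes, totals - successes) ~ yc,
               family = stats::binomial()))
  lr <- fit$null.deviance - fit$deviance
  separation <- any(abs(stats::coef(fit)) > 15) ||
    !fit$converged
  if (separation)
    warning("possible complete separation: estimates unreliable")
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 lr_chisq = lr,
                 p_value = stats::pchisq(lr, df = 1L, lower.tail = FALSE),
                 n_years = length(unique(years)),
                 separation = separation, glm = fit),
            class = "binomial_trend_fit")
}

#' @export
print.binomial_trend_fit <- function(x, ...) {
  cat(sprintf("Binomial year trend: slope %.4f logit/yr, LR chi-sq = %.2f (1 df), p = %.3g\n",
              x$slope, x$lr_chisq, x$p_value))
  invisible(x)
}

#' Reconstruct integer counts from published percentages
#'
#' When only a summary table (percentage and sample size per year) is
#' available, category counts are reconstructed as
#' \code{round(pct * n / 100)}. Exact counts should be used whenever raw
#' records exist; the reconstruction inherits the table's rounding error.
#'
#' @param pct Percentage per year (0-100).
#' @param n Sample size per year.
#' @return Integer counts.
#' @export
counts_from_percent <- function(pct, n) {
  stopifnot(all(pct >= 0 & pct <= 100), all(n >= 0))
  as.integer(round(pct * n / 100))
}

#' Random-intercept trend of landed length over years
#'
#' Fits the mixed model \code{tl_cm ~ year + (1 | source)} by maximum
#' likelihood: a common linear year trend in mean landed length, with a
#' normal random intercept per data source absorbing among-source level
#' differences. With a single source the model degenerates and an ordinary
#' linear regression is fitted instead (with a warning).
#'
#' @param ds A [length_dataset()] with at least 3 distinct years.
#' @return Object of class \code{"mixed_trend_fit"}: \code{slope} (cm per
#'   year) and \code{slope_se}, \code{source_sd} (among-source sd, cm),
#'   \code{resid_sd} (cm), \code{loglik}, \code{n_sources}, and the fitted
#'   \code{model}.
#' @export
fit_mixed_trend <- function(ds) {
  if (length(unique(ds$year)) < 3L) stop("need at least 3 distinct years")
  df <- as.data.frame(ds)
  df$year_c <- df$year - mean(df$year)
  if (length(unique(df$source)) < 2L) {
    warning("single data source: falling back to ordinary linear regression")
    fit <- stats::lm(tl_cm ~ year_c, data = df)
    sm <- summary(fit)
    return(structure(list(slope = unname(stats::coef(fit)[2L]),
                          slope_se = sm$coefficients[2L, 2L],
                          source_sd = 0, resid_sd = sm$sigma,
                          loglik = as.numeric(stats::logLik(fit)),
                          n_sources = 1L, model = fit),
                     class = "mixed_trend_fit"))
  }
  fit <- lme4::lmer(tl_cm ~ year_c + (1 | source), data = df, REML = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  sm <- summary(fit)
  structure(list(slope = unname(lme4::fixef(fit)[2L]),
                 slope_se = sm$coefficients[2L, 2L],
                 source_sd = vc$sdcor[vc$grp == "source"],
                 resid_sd = vc$sdcor[vc$grp == "Residual"],
                 loglik = as.numeric(stats::logLik(fit)),
                 n_sources = length(unique(df$source)), model = fit),
            class = "mixed_trend_fit")
}

#' @export
print.mixed_trend_fit <- function(x, ...) {
  cat(sprintf("Mixed year trend (TL ~ year + (1|source), ML):\n"))
  cat(sprintf("  slope %.3f cm/yr (se %.3f); among-source sd %.2f cm; residual sd %.2f cm\n",
              x$slope, x$slope_se, x$source_sd, x$resid_sd))
  invisible(x)
}

#' Parametric bootstrap test of the year effect on landed length
#'
#' Tests the year trend in the random-intercept model by parametric
#' bootstrap: the observed statistic is the likelihood-ratio
#' \eqn{2(\ell_{full} - \ell_{null})} between \code{tl ~ year + (1|source)}
#' and \code{tl ~ 1 + (1|source)}; its null distribution is built by
#' simulating response vectors from the fitted null model and refitting both
#' models to each. The p-value uses the plus-one rule
#' \eqn{p = (1 + \#\{stat^* \ge stat\}) / (B_{ok} + 1)}, so it is never
#' exactly zero. Replicates whose refits fail are dropped (warning above
#' 10\% failures).
#'
#' @param ds A [length_dataset()] with at least 2 sources and 3 years.
#' @param n_boot Bootstrap replicates; default 1000.
#' @param seed Integer seed fixing the simulation stream.
#' @return List with \code{pb_stat} (observed likelihood ratio),
#'   \code{pb_p}, \code{n_boot}, \code{n_failed}.
#' @export
parametric_bootstrap_test <- function(ds, n_boot = 1000, seed = 1L) {
  df <- as.data.frame(ds)
  df$year_c <- df$year - mean(df$year)
  if (length(unique(df$source)) < 2L) stop("need at least 2 data sources")
  full <- lme4::lmer(tl_cm ~ year_c + (1 | source), data = df, REML = FALSE)
  null <- lme4::lmer(tl_cm ~ 1 + (1 | source), data = df, REML = FALSE)
  obs <- 2 * (as.numeric(stats::logLik(full)) - as.numeric(stats::logLik(null)))
  sims <- stats::simulate(null, nsim = n_boot, seed = seed)
  stats_b <- vapply(seq_len(n_boot), function(i) {
    tryCatch({
      y <- sims[[i]]
      f <- suppressWarnings(suppressMessages(lme4::refit(full, y)))
      n0 <- suppressWarnings(suppressMessages(lme4::refit(null, y)))
      2 * (as.numeric(stats::logLik(f)) - as.numeric(stats::logLik(n0)))
    }, error = function(e) NA_real_)
  }, numeric(1L))
  ok <- stats_b[is.finite(stats_b)]
  n_failed <- n_boot - length(ok)
  if (n_failed > 0.1 * n_boot)
    warning(sprintf("%d of %d bootstrap refits failed", n_failed, n_boot))
  list(pb_stat = obs,
       pb_p = (1 + sum(ok >= obs)) / (length(ok) + 1),
       n_boot = n_boot, n_failed = n_failed)
}
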