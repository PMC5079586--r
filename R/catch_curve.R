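#' Assign an age to a length by inverting the growth curve
#'
#' Inverse von Bertalanffy age-length key:
#' \deqn{a = t_0 - \ln(1 - TL/L_\infty)/k}{a = t0 - ln(1 - TL/Linf)/k}
#' floored to an integer age class (age classes are right-open, consistent
#' with the half-open length binning used elsewhere) and capped at
#' \code{tmax}. Lengths at or above \eqn{L_\infty} cannot be inverted and map
#' to \code{tmax}; their number is reported in the \code{"n_capped"}
#' attribute.
#'
#' @param tl_cm Total length(s), cm, positive.
#' @param lh A [life_history()] object (uses \code{l_inf}, \code{k_growth},
#'   \code{t0}, \code{tmax}).
#' @return Integer age(s) in years, with attribute \code{n_capped}.
#' @examples
#' assign_age(46.8, bacalao_life_history())  # 5
#' @export
assign_age <- function(tl_cm, lh) {
  stopifnot(all(tl_cm > 0))
  capped <- tl_cm >= lh$l_inf
  a <- rep(lh$tmax, length(tl_cm))
  a[!capped] <- lh$t0 - log(1 - tl_cm[!capped] / lh$l_inf) / lh$k_growth
  age <- pmin(floor(a), lh$tmax)
  age <- pmax(age, 0)
  structure(as.integer(age), n_capped = sum(capped))
}

#' Build an age-frequency distribution for catch-curve analysis
#'
#' Converts lengths to integer ages via [assign_age()], tabulates catch at
#' age, locates the peak age (the first age of maximum catch), and extracts
#' the descending limb — only age classes fully recruited to the gear, i.e.
#' ages from the peak onward (optionally from one past the peak) — with ages
#' recoded to start at 0 as the Chapman-Robson estimator requires.
#'
#' @param ds A [length_dataset()] (or a numeric vector of ages via
#'   \code{ages}).
#' @param lh A [life_history()] object.
#' @param limb Either \code{"peak"} (limb starts at the peak age; default) or
#'   \code{"peak_plus_one"}.
#' @param ages Optional integer ages, bypassing length-to-age conversion.
#' @return Object of class \code{"age_frequency"}: \code{ages},
#'   \code{counts} (all ages), \code{peak_age}, \code{descending_limb}
#'   (ages used), \code{limb_counts}, \code{recoded} (limb ages minus the
#'   first limb age).
#' @export
build_age_frequency <- function(ds = NULL, lh = NULL,
                                limb = c("peak", "peak_plus_one"),
                                ages = NULL) {
  limb <- match.arg(limb)
  if (is.null(ages)) {
    stopifnot(!is.null(ds), nrow(ds) > 0L, !is.null(lh))
    ages <- assign_age(ds$tl_cm, lh)
  }
  tab <- table(factor(ages, levels = seq(min(ages), max(ages))))
  age_vals <- as.integer(names(tab))
  counts <- as.integer(tab)
  if (length(age_vals) < 2L) stop("no descending limb: all fish in one age class")
  peak <- age_vals[which.max(counts)]
  start <- if (limb == "peak") peak else peak + 1L
  sel <- age_vals >= start
  if (sum(sel) < 2L) stop("no descending limb: fewer than 2 age classes after the peak")
  structure(list(ages = age_vals, counts = counts, peak_age = peak,
                 descending_limb = age_vals[sel],
                 limb_counts = counts[sel],
                 recoded = age_vals[sel] - start),
            class = "age_frequency")
}

#' @export
print.age_frequency <- function(x, ...) {
  cat("Age frequency (catch at age):\n")
  print(stats::setNames(x$counts, x$ages))
  cat(sprintf("  peak age %d; descending limb %d-%d (%d fish)\n",
              x$peak_age, min(x$descending_limb), max(x$descending_limb),
              sum(x$limb_counts)))
  invisible(x)
}

#' Chapman-Robson survival and bias-corrected total mortality
#'
#' From the descending limb of a catch curve with \eqn{n} fish and recoded-age
#' sum \eqn{T}, the Chapman-Robson estimate of annual survival is
#' \deqn{\hat S = T / (n + T - 1)}{S = T/(n + T - 1)}
#' and instantaneous total mortality uses the bias-corrected form
#' \deqn{\hat Z = -\log(\hat S) - \frac{(n-1)(n-2)}{n(T+1)(n+T-1)}}{
#' Z = -log(S) - (n-1)(n-2) / (n (T+1) (n+T-1))}
#' Standard errors: \eqn{SE(\hat S) = \sqrt{\hat S(\hat S - (T-1)/(n+T-2))}}
#' (the estimator's exact small-sample variance) and
#' \eqn{SE(\hat Z) = (1-\hat S)/\sqrt{n \hat S}}.
#'
#' @param af An [build_age_frequency()] object (or a named list with
#'   \code{limb_counts} and \code{recoded}).
#' @return Object of class \code{"mortality_estimate"}: \code{s_annual}
#'   (fraction), \code{z_total} (1/yr), \code{se_s}, \code{se_z},
#'   \code{n_used}, \code{t_sum}, \code{degenerate} (TRUE when all limb fish
#'   sit at the peak age, giving S = 0).
#' @examples
#' af <- list(limb_counts = c(4, 2, 1), recoded = c(0, 1, 2))
#' chapman_robson(af)  # S = 4/10 = 0.4
#' @export
chapman_robson <- function(af) {
  counts <- af$limb_counts
  rec <- af$recoded
  if (length(counts) < 2L) stop("descending limb has fewer than 2 age classes")
  n <- sum(counts)
  if (n < 3L) stop("descending limb has fewer than 3 fish")
  T <- sum(rec * counts)
  S <- T / (n + T - 1)
  degenerate <- T == 0
  Z <- if (degenerate) Inf
       else -log(S) - (n - 1) * (n - 2) / (n * (T + 1) * (n + T - 1))
  se_s <- sqrt(max(S * (S - (T - 1) / (n + T - 2)), 0))
  se_z <- if (degenerate) NA_real_ else (1 - S) / sqrt(n * S)
  structure(list(s_annual = S, z_total = Z, se_s = se_s, se_z = se_z,
                 n_used = n, t_sum = T, degenerate = degenerate),
            class = "mortality_estimate")
}

#' @export
print.mortality_estimate <- function(x, ...) {
  cat("Chapman-Robson mortality estimate:\n")
  cat(sprintf("  annual survival S = %.1f%% (se %.1f%%)\n",
              100 * x$s_annual, 100 * x$se_s))
  cat(sprintf("  total mortality Z = %.2f /yr (se %.2f)\n", x$z_total, x$se_z))
  cat(sprintf("  limb: n = %d fish, recoded-age sum T = %d%s\n",
              x$n_used, x$t_sum,
              if (x$degenerate) "  [degenerate: all fish at peak age]" else ""))
  invisible(x)
}

#' Mean generational turnover time
#'
#' Average time for a new generation to replace the previous one, from female
#' age at maturity and maximum age:
#' \deqn{\bar{GT} = AM + (T_{max} - AM)/2}{GT = AM + (Tmax - AM)/2}
#'
#' @param am Female age at maturity (yr), nonnegative.
#' @param tmax Maximum age (yr), at least \code{am}.
#' @return Object of class \code{"turnover_estimate"} with \code{gt_years}
#'   at full precision (display rounds to 1 decimal).
#' @examples
#' generational_turnover(6.5, 21)  # 13.75 yr
#' @export
generational_turnover <- function(am, tmax) {
  if (!(am >= 0)) stop("'am' must be nonnegative")
  if (am > tmax) stop("'am' must not exceed 'tmax'")
  structure(list(gt_years = am + (tmax - am) / 2, am = am, tmax = tmax),
            class = "turnover_estimate")
}

#' @export
print.turnover_estimate <- function(x, ...) {
  cat(sprintf("Generational turnover: %.1f yr (AM = %.1f, Tmax = %.1f)\n",
              x$gt_years, x$am, x$tmax))
  invisible(x)
}
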