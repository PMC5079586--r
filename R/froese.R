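#' Optimum harvest length and the mega-spawner threshold
#'
#' Computes Froese's optimum length from the empirical relationship
#' \deqn{L_{opt} = 10^{1.0421 \log_{10}(L_\infty) - 0.2742}}{
#'   Lopt = 10^(1.0421*log10(Linf) - 0.2742)}
#' together with the optimum length interval (plus/minus 10\% of Lopt) and the
#' mega-spawner threshold (the interval's upper bound: mega-spawners are fish
#' longer than Lopt + 10\%).
#'
#' @param l_inf Asymptotic length (cm), positive.
#' @return An object of class \code{"optimal_length"}: list with \code{lopt},
#'   \code{lo} (= 0.9 Lopt), \code{hi} (= 1.1 Lopt) and
#'   \code{mega_threshold} (= \code{hi}), all full precision.
#' @examples
#' compute_lopt(110)  # Lopt 71.3 cm, interval 64.2-78.4 cm
#' @export
compute_lopt <- function(l_inf) {
  if (!is.numeric(l_inf) || length(l_inf) != 1L || !is.finite(l_inf) || l_inf <= 0)
    stop("'l_inf' must be a single positive number")
  lopt <- 10^(1.0421 * log10(l_inf) - 0.2742)
  structure(list(lopt = lopt, lo = 0.9 * lopt, hi = 1.1 * lopt,
                 mega_threshold = 1.1 * lopt),
            class = "optimal_length")
}

#' @export
print.optimal_length <- function(x, ...) {
  cat(sprintf("Lopt = %.1f cm; optimum interval %.1f-%.1f cm; mega-spawners > %.1f cm\n",
              x$lopt, x$lo, x$hi, x$mega_threshold))
  invisible(x)
}

#' Classify fish lengths against maturity and optimum-length references
#'
#' Boundary conventions: mature means TL >= \code{lm50} (boundary fish count
#' as mature); the optimum interval is closed, \code{lo <= TL <= hi}; a
#' mega-spawner is strictly longer than the threshold. Since the threshold
#' exceeds \code{lm50}, every mega-spawner is also mature, and a mega-spawner
#' is by definition outside the optimum interval.
#'
#' @param tl_cm Vector of total lengths (cm).
#' @param lm50 Length at 50\% maturity (cm).
#' @param opt An [compute_lopt()] result.
#' @return A data.frame with logical columns \code{mature}, \code{in_opt},
#'   \code{mega}, one row per fish.
#' @export
classify_fish <- function(tl_cm, lm50, opt) {
  stopifnot(all(tl_cm > 0), lm50 > 0)
  data.frame(mature = tl_cm >= lm50,
             in_opt = tl_cm >= opt$lo & tl_cm <= opt$hi,
             mega = tl_cm > opt$mega_threshold)
}

#' Per-year catch-composition sustainability indicators
#'
#' For each year in the dataset, computes the three catch-based indicators of
#' stock health: percentage of the catch at or above the length at maturity,
#' percentage within the optimum length interval, and percentage of
#' mega-spawners, alongside sample size and mean/sd of landed length.
#' Percentages are carried at full precision (round only for display).
#'
#' @param ds A [length_dataset()].
#' @param lh A [life_history()] (supplies \code{lm50}).
#' @param opt Optimum-length reference; default derived from \code{lh$l_inf}.
#' @return A data.frame ordered by year with columns \code{year}, \code{n},
#'   \code{pct_mature}, \code{pct_opt}, \code{pct_mega}, \code{mean_tl},
#'   \code{sd_tl}.
#' @examples
#' ds <- length_dataset(2012, "toy", c(60, 66, 70, 80))
#' compute_indicators(ds, bacalao_life_history())
#' @export
compute_indicators <- function(ds, lh, opt = compute_lopt(lh$l_inf)) {
  if (nrow(ds) == 0L) stop("empty dataset")
  base <- summarize_by_year(ds)
  cls <- classify_fish(ds$tl_cm, lh$lm50, opt)
  pct <- function(flag, y) 100 * sum(flag[ds$year == y]) / sum(ds$year == y)
  base$pct_mature <- vapply(base$year, function(y) pct(cls$mature, y), 0)
  base$pct_opt <- vapply(base$year, function(y) pct(cls$in_opt, y), 0)
  base$pct_mega <- vapply(base$year, function(y) pct(cls$mega, y), 0)
  base[, c("year", "n", "pct_mature", "pct_opt", "pct_mega",
           "mean_tl", "sd_tl")]
}

#' Health flags for an indicator row
#'
#' Applies the reference levels of the indicator framework: a healthy,
#' unregulated stock should show (practically) all landed fish mature, a very
#' large share inside the optimum interval, and roughly 30-40\% mega-spawners.
#'
#' @param row A single row of [compute_indicators()] output (or a data.frame;
#'   flags are vectorised over rows).
#' @param opt_healthy Minimum healthy percentage inside the optimum interval;
#'   default 90.
#' @param mega_healthy Minimum healthy mega-spawner percentage; default 30.
#' @return data.frame of logical flags \code{recruitment_overfishing}
#'   (some immature fish in the catch), \code{growth_overfishing}
#'   (optimum-interval share below \code{opt_healthy}),
#'   \code{mega_spawner_deficit} (below \code{mega_healthy}).
#' @export
health_flags <- function(row, opt_healthy = 90, mega_healthy = 30) {
  data.frame(year = row$year,
             recruitment_overfishing = row$pct_mature < 100,
             growth_overfishing = row$pct_opt < opt_healthy,
             mega_spawner_deficit = row$pct_mega < mega_healthy)
}
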