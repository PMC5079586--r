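#' Equilibrium age-structured population
#'
#' Relative numbers-at-age of a constant-recruitment population at
#' equilibrium under natural mortality M and length-based fishing mortality
#' \eqn{F S(L_a)} with \eqn{F = (F/M) M}: age 0 has relative number 1 and
#' \deqn{N_a = \prod_{a' < a} e^{-(M + F S(L_{a'}))}}{
#' N_a = prod over a' < a of exp(-(M + F S(L_a')))}
#' Mean length at age follows von Bertalanffy growth; length variability at
#' age is sd = CV Linf times mean length.
#'
#' @param lh A [life_history()] object.
#' @param f_over_m Fishing-to-natural mortality ratio F/M, nonnegative.
#' @param sel A [selectivity_params()] object.
#' @param age_step Age step in years (default 1, annual classes 0..tmax).
#' @return Object of class \code{"population_state"}: \code{ages},
#'   \code{rel_numbers} (non-increasing, age 0 = 1), \code{mean_len_at_age},
#'   \code{sd_len_at_age}.
#' @examples
#' pop <- equilibrium_population(bacalao_life_history(), 0,
#'                               selectivity_params(39, 46.7))
#' all.equal(pop$rel_numbers, exp(-0.29 * pop$ages))
#' @export
equilibrium_population <- function(lh, f_over_m, sel, age_step = 1) {
  stopifnot(f_over_m >= 0)
  ages <- seq(0, lh$tmax, by = age_step)
  ml <- length_at_age(ages, lh)
  za <- lh$m_nat + f_over_m * lh$m_nat * selectivity_at_length(ml, sel)
  structure(list(ages = ages,
                 rel_numbers = .survivorship(za, age_step),
                 mean_len_at_age = ml,
                 sd_len_at_age = lh$cv_linf * ml),
            class = "population_state")
}

#' Sample catch lengths from an equilibrium population
#'
#' The observation model inverted by the LB-SPR fit: each landed fish is
#' drawn by (i) sampling an age with probability proportional to relative
#' numbers-at-age times gear selectivity at that age's mean length, then
#' (ii) drawing a length from that age's normal length distribution,
#' truncated at zero (exact inverse-CDF draw). Ages whose mean length is not
#' yet positive (below \code{t0}) cannot appear in the catch and get weight
#' zero. Identical seeds give identical datasets.
#'
#' @param pop An [equilibrium_population()] result.
#' @param sel A [selectivity_params()] object.
#' @param n Number of fish to draw, at least 1.
#' @param seed Integer random seed.
#' @param year Calendar year stamped on the records; default 2012.
#' @param source Source label; default \code{"sim"}.
#' @return A [length_dataset()] of \code{n} records.
#' @export
sample_catch_lengths <- function(pop, sel, n, seed, year = 2012L,
                                 source = "sim") {
  stopifnot(n >= 1)
  w <- pop$rel_numbers * selectivity_at_length(pop$mean_len_at_age, sel)
  w[pop$mean_len_at_age <= 0] <- 0
  if (!any(w > 0)) stop("no catchable fish: selectivity-weighted numbers are all zero")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  idx <- sample.int(length(pop$ages), n, replace = TRUE, prob = w)
  m <- pop$mean_len_at_age[idx]
  s <- pop$sd_len_at_age[idx]
  # exact zero-truncated normal via inverse CDF; sd = 0 collapses to the mean
  u <- stats::runif(n, stats::pnorm(0, m, s), 1)
  tl <- ifelse(s > 0, stats::qnorm(u, m, s), m)
  length_dataset(rep(year, n), source, tl,
                 provenance = sprintf("simulated (seed %d)", seed))
}

#' Simulation scenario for a multi-year length time series
#'
#' @param life_history A [life_history()] object.
#' @param years Calendar years to simulate.
#' @param f_over_m F/M per year: scalar (recycled) or one value per year,
#'   each nonnegative.
#' @param sel A [selectivity_params()] object.
#' @param n_per_year Sample size per year (scalar or per-year), at least 1.
#' @param seed Integer seed; per-year draws use \code{seed + year index}.
#' @return Object of class \code{"sim_scenario"}.
#' @export
sim_scenario <- function(life_history, years, f_over_m, sel, n_per_year,
                         seed = 1L) {
  stopifnot(all(f_over_m >= 0), all(n_per_year >= 1))
  f_over_m <- rep_len(f_over_m, length(years))
  n_per_year <- rep_len(n_per_year, length(years))
  structure(list(life_history = life_history, years = years,
                 f_over_m = f_over_m, sel = sel, n_per_year = n_per_year,
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Simulate a multi-year length-composition time series
#'
#' One equilibrium population per year (each year's F/M), sampled
#' independently; records carry the scenario's calendar years and a
#' \code{"sim"} source label.
#'
#' @param scenario A [sim_scenario()].
#' @return A [length_dataset()].
#' @export
simulate_timeseries <- function(scenario) {
  if (length(scenario$years) == 0L) {
    warning("empty years list: returning empty dataset")
    return(length_dataset(integer(), character(), numeric(),
                          provenance = "simulated (empty scenario)"))
  }
  parts <- lapply(seq_along(scenario$years), function(i) {
    pop <- equilibrium_population(scenario$life_history,
                                  scenario$f_over_m[i], scenario$sel)
    sample_catch_lengths(pop, scenario$sel, scenario$n_per_year[i],
                         seed = scenario$seed + i,
                         year = scenario$years[i])
  })
  out <- do.call(rbind.data.frame, lapply(parts, as.data.frame))
  length_dataset(out$year, out$source, out$tl_cm,
                 provenance = sprintf("simulated time series (seed %d)",
                                      scenario$seed))
}
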