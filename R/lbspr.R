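#' Logistic selectivity parameters
#'
#' @param sl50 Length at 50\% selectivity (cm).
#' @param sl95 Length at 95\% selectivity (cm); must exceed \code{sl50}.
#' @return An object of class \code{"selectivity_params"}.
#' @export
selectivity_params <- function(sl50, sl95) {
  if (!(is.finite(sl50) && is.finite(sl95) && sl50 > 0 && sl95 > sl50))
    stop("need 0 < sl50 < sl95")
  structure(list(sl50 = sl50, sl95 = sl95), class = "selectivity_params")
}

#' @export
print.selectivity_params <- function(x, ...) {
  cat(sprintf("Logistic selectivity: SL50 = %.1f cm, SL95 = %.1f cm\n",
              x$sl50, x$sl95))
  invisible(x)
}

# 50/95-anchored logistic: f(l50) = 0.5, f(l95) = 0.95 by construction.
.logistic5095 <- function(l, l50, l95) {
  1 / (1 + exp(-log(19) * (l - l50) / (l95 - l50)))
}

#' Gear selectivity at length
#'
#' Asymptotic (non-dome) logistic selectivity anchored at its 50\% and 95\%
#' points: \deqn{S(l) = \frac{1}{1 + e^{-\ln(19)(l - SL50)/(SL95 - SL50)}}}{
#' S(l) = 1/(1 + exp(-ln(19) (l - SL50)/(SL95 - SL50)))}
#' so that \eqn{S(SL50) = 0.5} and \eqn{S(SL95) = 0.95} exactly.
#'
#' @param l Length(s), cm.
#' @param sel A [selectivity_params()] object.
#' @return Selection probability in (0, 1), vectorised over \code{l}.
#' @examples
#' selectivity_at_length(c(39, 46.7), selectivity_params(39, 46.7))
#' @export
selectivity_at_length <- function(l, sel) {
  .logistic5095(l, sel$sl50, sel$sl95)
}

#' Maturity ogive at length
#'
#' Same ln(19)-anchored logistic as [selectivity_at_length()], anchored at
#' the life history's \code{lm50} and \code{lm95}.
#'
#' @param l Length(s), cm.
#' @param lh A [life_history()] object.
#' @return Proportion mature in (0, 1).
#' @export
maturity_at_length <- function(l, lh) {
  .logistic5095(l, lh$lm50, lh$lm95)
}

#' Default length bins for a life history
#'
#' Half-open bins \code{[lo, hi)} of constant width from 0 to just past
#' 1.3 times the asymptotic length (so the upper tail of length-at-age
#' variability is always covered).
#'
#' @param lh A [life_history()] object.
#' @param width Bin width in cm; default 2.
#' @param max_mult Upper edge as a multiple of \code{l_inf}; default 1.3.
#' @return Numeric vector of bin edges.
#' @export
make_length_bins <- function(lh, width = 2, max_mult = 1.3) {
  upper <- ceiling(max_mult * lh$l_inf / width) * width
  seq(0, upper, by = width)
}

#' Bin raw lengths into a length composition
#'
#' @param tl_cm Raw fish lengths (cm), or \code{NULL} if \code{counts} given.
#' @param bin_edges Ordered bin edges; bins are half-open \code{[lo, hi)}.
#' @param counts Alternatively, per-bin counts (length
#'   \code{length(bin_edges) - 1}).
#' @return Object of class \code{"length_composition"}: list with
#'   \code{bin_edges}, \code{mids}, \code{counts}, \code{prop}.
#' @export
length_composition <- function(tl_cm = NULL, bin_edges, counts = NULL) {
  stopifnot(length(bin_edges) >= 2L, !is.unsorted(bin_edges, strictly = TRUE))
  nb <- length(bin_edges) - 1L
  if (is.null(counts)) {
    stopifnot(!is.null(tl_cm))
    idx <- findInterval(tl_cm, bin_edges)
    out_of_range <- idx < 1L | idx > nb
    if (any(out_of_range))
      warning(sum(out_of_range), " fish outside the bin range were dropped")
    counts <- tabulate(idx[!out_of_range], nbins = nb)
  } else {
    stopifnot(length(counts) == nb, all(counts >= 0))
  }
  tot <- sum(counts)
  structure(list(bin_edges = bin_edges,
                 mids = (bin_edges[-1] + bin_edges[-(nb + 1L)]) / 2,
                 counts = counts,
                 prop = if (tot > 0) counts / tot else counts),
            class = "length_composition")
}

#' Growth-type-group model setup
#'
#' Precomputes everything about the per-recruit model that does not depend on
#' fishing mortality or selectivity: the growth-type groups (sub-cohorts with
#' L-infinity values equally spaced across plus/minus \code{sd_range} standard
#' deviations of Normal(Linf, CV Linf), weighted by the normal density), their
#' mean lengths-at-age, per-age probabilities of falling in each length bin
#' (normal length-at-age with sd = CV times mean length), and the
#' maturity-weighted relative fecundity at age. Used internally by
#' [expected_length_composition()], [spawning_potential_ratio()] and
#' [fit_lbspr()]; exposed so repeated fits can share the setup.
#'
#' @param lh A [life_history()] object.
#' @param bin_edges Length-bin edges, e.g. [make_length_bins()].
#' @param n_gtg Number of growth-type groups; default 13. Use 1 for a
#'   single-cohort (no growth variability) model.
#' @param sd_range Half-width of the group grid in standard deviations;
#'   default 2.5.
#' @param age_step Age step in years; default 1 (annual age classes
#'   0..tmax).
#' @return A list used by the per-recruit functions.
#' @export
gtg_setup <- function(lh, bin_edges, n_gtg = 13, sd_range = 2.5,
                      age_step = 1) {
  stopifnot(n_gtg >= 1, sd_range > 0, age_step > 0)
  if (!is.finite(lh$tmax)) stop("life history needs 'tmax' for age-structured sums")
  ages <- seq(0, lh$tmax, by = age_step)
  x <- if (n_gtg == 1L) 0 else seq(-sd_range, sd_range, length.out = n_gtg)
  w <- stats::dnorm(x)
  w <- w / sum(w)
  linfs <- lh$l_inf + x * lh$cv_linf * lh$l_inf
  if (any(linfs <= 0)) stop("growth-type group with nonpositive Linf; lower cv_linf or sd_range")
  nb <- length(bin_edges) - 1L
  la <- lapply(linfs, function(li) length_at_age(ages, lh, l_inf = li))
  # P[[g]][a, b]: probability a fish of age a (group g) lies in length bin b.
  # pnorm handles sd = 0 (age at t0) as a point mass.
  P <- lapply(seq_along(linfs), function(g) {
    m <- la[[g]]
    s <- lh$cv_linf * m
    cdf <- vapply(seq_along(ages),
                  function(a) stats::pnorm(bin_edges, m[a], s[a]),
                  numeric(nb + 1L))
    t(cdf[-1L, , drop = FALSE] - cdf[-(nb + 1L), , drop = FALSE])
  })
  list(lh = lh, ages = ages, age_step = age_step, weights = w,
       linfs = linfs, la = la, P = P, bin_edges = bin_edges,
       mids = (bin_edges[-1] + bin_edges[-(nb + 1L)]) / 2)
}

# Survivorship-to-age given per-age total mortality (vector za, per year),
# scaled by the age step: survivorship at the first age is 1.
.survivorship <- function(za, age_step) {
  n <- length(za)
  exp(-cumsum(c(0, za[-n] * age_step)))
}

#' Expected catch length composition under the per-recruit model
#'
#' The observation model of the length-based SPR method: within each
#' growth-type group, equilibrium numbers-at-age follow survivorship under
#' total mortality \eqn{Z_a = M + F S(L_a)} (with \eqn{F = (F/M) M} and
#' \eqn{L_a} the group's mean length at age); numbers are spread over length
#' bins by each age's normal length distribution, weighted by gear
#' selectivity at the bin midpoint, combined across groups by their
#' recruitment weights, and normalised to proportions.
#'
#' @param lh A [life_history()] object.
#' @param f_over_m Fishing-to-natural mortality ratio F/M (nonnegative).
#' @param sel A [selectivity_params()] object.
#' @param bin_edges Length-bin edges; default [make_length_bins()].
#' @param n_gtg,sd_range,age_step Growth-type-group controls, see
#'   [gtg_setup()].
#' @param setup Optional precomputed [gtg_setup()] (overrides the previous
#'   three arguments).
#' @return A \code{"length_composition"} whose \code{prop} sums to 1 (counts
#'   slot holds the unnormalised relative catch).
#' @export
expected_length_composition <- function(lh, f_over_m, sel,
                                        bin_edges = make_length_bins(lh),
                                        n_gtg = 13, sd_range = 2.5,
                                        age_step = 1, setup = NULL) {
  stopifnot(f_over_m >= 0)
  if (is.null(setup)) setup <- gtg_setup(lh, bin_edges, n_gtg, sd_range, age_step)
  lh <- setup$lh
  f_abs <- f_over_m * lh$m_nat
  sel_mid <- selectivity_at_length(setup$mids, sel)
  catch <- numeric(length(setup$mids))
  for (g in seq_along(setup$weights)) {
    la <- setup$la[[g]]
    za <- lh$m_nat + f_abs * selectivity_at_length(la, sel)
    n_at_age <- .survivorship(za, setup$age_step)
    catch <- catch + setup$weights[g] *
      as.vector(crossprod(setup$P[[g]], n_at_age)) * sel_mid
  }
  tot <- sum(catch)
  if (tot <= 0) stop("degenerate model: expected composition has zero mass")
  length_composition(bin_edges = setup$bin_edges, counts = catch)
}

#' Spawning potential ratio
#'
#' Lifetime egg production per recruit under fishing relative to the unfished
#' value:
#' \deqn{SPR = P_{fished} / P_{unfished}}{SPR = P_fished / P_unfished}
#' with \eqn{P_{unfished} = \sum_a E_a e^{-M a}} and the fished sum using
#' survivorship under \eqn{Z_a = M + F S(L_a)}. Egg production at age
#' integrates the fecundity-length power law over the age's length
#' distribution, \eqn{E_a = \sum_l P(l \mid a)\, Mat(l)\, l^b} (length
#' variability at age is what a length-based method propagates; evaluating
#' maturity at the mean length alone understates the egg production of
#' young, partially mature ages). Computed per growth-type group and
#' combined with the group weights; recruitment-independent (per recruit) by
#' construction, so \eqn{SPR \in [0, 1]} and \eqn{SPR = 1} exactly when
#' \eqn{F = 0}.
#'
#' @inheritParams expected_length_composition
#' @return SPR in \code{[0, 1]}.
#' @examples
#' lh <- bacalao_life_history()
#' spawning_potential_ratio(lh, 0, selectivity_params(39, 46.7))    # 1
#' spawning_potential_ratio(lh, 1.98, selectivity_params(39, 46.7)) # ~0.05
#' @export
spawning_potential_ratio <- function(lh, f_over_m, sel,
                                     n_gtg = 13, sd_range = 2.5,
                                     age_step = 1, setup = NULL) {
  stopifnot(f_over_m >= 0)
  if (is.null(setup))
    setup <- gtg_setup(lh, make_length_bins(lh, width = 1), n_gtg, sd_range,
                       age_step)
  lh <- setup$lh
  f_abs <- f_over_m * lh$m_nat
  fec_l <- maturity_at_length(setup$mids, lh) * setup$mids^lh$fec_b
  p_f <- 0
  p_u <- 0
  for (g in seq_along(setup$weights)) {
    la <- setup$la[[g]]
    e_a <- as.vector(setup$P[[g]] %*% fec_l)
    za <- lh$m_nat + f_abs * selectivity_at_length(la, sel)
    surv_f <- .survivorship(za, setup$age_step)
    surv_u <- exp(-lh$m_nat * setup$ages)
    p_f <- p_f + setup$weights[g] * sum(e_a * surv_f)
    p_u <- p_u + setup$weights[g] * sum(e_a * surv_u)
  }
  p_f / p_u
}

#' Fit the length-based SPR model to an observed length composition
#'
#' Maximum-likelihood estimation of relative fishing mortality (F/M) and
#' logistic gear selectivity (SL50, SL95) from a single length composition,
#' given the life history (M/k, Linf, CV Linf). The multinomial
#' log-likelihood \eqn{\sum_b n_b \log p_b(F/M, SL50, SL95)} is maximised by
#' Nelder-Mead simplex search over the transformed parameters
#' (log F/M, log SL50, log(SL95 - SL50)), from three deterministic starting
#' points, with a polishing restart from the best optimum. The spawning
#' potential ratio is evaluated at the optimum. Uncertainty is estimated by a
#' nonparametric bootstrap over individual fish (multinomial resampling of
#' the binned counts), refitting each resample.
#'
#' @param obs A [length_composition()] with counts (at least 3 non-empty
#'   bins; a warning is given below 50 fish).
#' @param lh A [life_history()] object.
#' @param start Optional starting values \code{c(f_over_m, sl50, sl95)}.
#' @param n_gtg,sd_range,age_step Growth-type-group controls.
#' @param n_boot Bootstrap replicates for SDs; default 100. Set 0 to skip.
#' @param seed Seed for the bootstrap resampling stream.
#' @param reltol Relative convergence tolerance on the log-likelihood for the
#'   simplex search; default 1e-8.
#' @return An object of class \code{"lbspr_fit"}: estimates
#'   \code{f_over_m}, \code{sel}, \code{spr}, \code{loglik},
#'   \code{converged}, \code{at_boundary} (F/M estimated at the zero-fishing
#'   boundary), bootstrap SDs (\code{sd_f_over_m}, \code{sd_sl50},
#'   \code{sd_sl95}, \code{sd_spr}), the observed and fitted compositions,
#'   and \code{n_fish}.
#' @examples
#' \donttest{
#' lh <- bacalao_life_history()
#' truth <- expected_length_composition(lh, 2, selectivity_params(39, 47))
#' obs <- length_composition(bin_edges = truth$bin_edges,
#'                           counts = round(truth$prop * 1e5))
#' fit_lbspr(obs, lh, n_boot = 0)
#' }
#' @export
fit_lbspr <- function(obs, lh, start = NULL, n_gtg = 13, sd_range = 2.5,
                      age_step = 1, n_boot = 100, seed = 1, reltol = 1e-8) {
  stopifnot(inherits(obs, "length_composition"))
  if (sum(obs$counts > 0) < 3L) stop("need at least 3 non-empty length bins")
  n_fish <- sum(obs$counts)
  if (n_fish < 50) warning("fewer than 50 fish; estimates will be imprecise")
  setup <- gtg_setup(lh, obs$bin_edges, n_gtg, sd_range, age_step)

  nll <- function(theta) {
    fm <- exp(theta[1L])
    sl50 <- exp(theta[2L])
    delta <- exp(theta[3L])
    if (!is.finite(fm) || !is.finite(sl50) || !is.finite(delta)) return(1e10)
    sel <- list(sl50 = sl50, sl95 = sl50 + delta)
    p <- expected_length_composition(lh, fm, sel, setup = setup)$prop
    -sum(obs$counts * log(pmax(p, 1e-12)))
  }

  # Deterministic multi-starts anchored on the observed composition quantiles
  cum <- cumsum(obs$prop)
  qn <- function(q) obs$mids[which(cum >= q)[1L]]
  width <- diff(obs$bin_edges[1:2])
  starts <- if (!is.null(start)) {
    list(c(log(start[1L]), log(start[2L]), log(start[3L] - start[2L])))
  } else {
    lapply(list(c(0.5, 0.15), c(1.0, 0.25), c(2.5, 0.40)), function(s) {
      sl50 <- max(qn(s[2L]), width)
      delta <- max(qn(min(s[2L] + 0.25, 0.9)) - sl50, width)
      c(log(s[1L]), log(sl50), log(delta))
    })
  }

  fits <- lapply(starts, function(th0)
    stats::optim(th0, nll, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = reltol)))
  best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
  # polish: restart the simplex at the incumbent optimum
  best <- stats::optim(best$par, nll, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = reltol))
  converged <- best$convergence == 0L
  est <- c(f_over_m = exp(best$par[1L]), sl50 = exp(best$par[2L]),
           sl95 = exp(best$par[2L]) + exp(best$par[3L]))
  sel_hat <- selectivity_params(est[["sl50"]], est[["sl95"]])
  spr_hat <- if (converged)
    spawning_potential_ratio(lh, est[["f_over_m"]], sel_hat, setup = setup)
  else NA_real_
  fitted <- expected_length_composition(lh, est[["f_over_m"]], sel_hat,
                                        setup = setup)

  boot <- NULL
  if (n_boot > 0 && converged) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    boot <- t(vapply(seq_len(n_boot), function(i) {
      cts <- as.vector(stats::rmultinom(1L, n_fish, obs$prop))
      bo <- list(bin_edges = obs$bin_edges, counts = cts)
      bnll <- function(theta) {
        fm <- exp(theta[1L]); sl50 <- exp(theta[2L]); delta <- exp(theta[3L])
        if (!all(is.finite(c(fm, sl50, delta)))) return(1e10)
        p <- expected_length_composition(
          lh, fm, list(sl50 = sl50, sl95 = sl50 + delta), setup = setup)$prop
        -sum(cts * log(pmax(p, 1e-12)))
      }
      bf <- stats::optim(best$par, bnll, method = "Nelder-Mead",
                         control = list(maxit = 1000, reltol = reltol))
      fm_b <- exp(bf$par[1L]); sl50_b <- exp(bf$par[2L])
      sl95_b <- sl50_b + exp(bf$par[3L])
      spr_b <- spawning_potential_ratio(
        lh, fm_b, list(sl50 = sl50_b, sl95 = sl95_b), setup = setup)
      c(fm_b, sl50_b, sl95_b, spr_b)
    }, numeric(4L)))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }

  structure(list(
    f_over_m = unname(est[["f_over_m"]]), sel = sel_hat,
    spr = unname(spr_hat), loglik = -best$value, converged = converged,
    at_boundary = est[["f_over_m"]] < 1e-3,
    sd_f_over_m = if (!is.null(boot)) stats::sd(boot[, 1L]) else NA_real_,
    sd_sl50 = if (!is.null(boot)) stats::sd(boot[, 2L]) else NA_real_,
    sd_sl95 = if (!is.null(boot)) stats::sd(boot[, 3L]) else NA_real_,
    sd_spr = if (!is.null(boot)) stats::sd(boot[, 4L]) else NA_real_,
    n_boot = n_boot, n_fish = n_fish, obs = obs, fitted = fitted,
    n_gtg = n_gtg), class = "lbspr_fit")
}

#' @export
print.lbspr_fit <- function(x, ...) {
  cat("Length-based SPR fit\n")
  cat(sprintf("  n = %d fish, %d growth-type groups, logLik = %.2f%s\n",
              x$n_fish, x$n_gtg, x$loglik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  fmt <- function(v, s) if (is.na(s)) sprintf("%.3g", v)
                        else sprintf("%.3g (+/- %.2g SD)", v, s)
  cat("  F/M  =", fmt(x$f_over_m, x$sd_f_over_m),
      if (x$at_boundary) " [at zero-fishing boundary]" else "", "\n")
  cat("  SL50 =", fmt(x$sel$sl50, x$sd_sl50), "cm\n")
  cat("  SL95 =", fmt(x$sel$sl95, x$sd_sl95), "cm\n")
  cat("  SPR  =", fmt(x$spr, x$sd_spr), "\n")
  invisible(x)
}
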