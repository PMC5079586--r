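#' Life-history parameter set
#'
#' Bundles the biological parameters needed by the length-based assessment
#' tools: von Bertalanffy growth (\code{l_inf}, \code{k_growth}, \code{t0}),
#' individual growth variability (\code{cv_linf}), natural mortality
#' (\code{m_nat}) and the key life-history ratio \code{m_over_k}, the maturity
#' ogive (\code{lm50}, \code{lm95}), a fecundity-length exponent
#' (\code{fec_b}), and the ages used for turnover and age-structured sums
#' (\code{am}, \code{tmax}).
#'
#' Any two of \code{m_nat}, \code{k_growth}, \code{m_over_k} determine the
#' third; supply at least two and the missing one is derived. If all three are
#' given they must agree to within 1e-9.
#'
#' @param l_inf Asymptotic length L-infinity (cm); mean maximum length of the
#'   von Bertalanffy growth curve.
#' @param lm50 Length at 50\% maturity (cm).
#' @param m_nat Instantaneous natural mortality M (1/yr).
#' @param k_growth Brody growth coefficient k (1/yr).
#' @param m_over_k Ratio M/k (dimensionless), the central input of
#'   length-based per-recruit methods.
#' @param cv_linf Coefficient of variation of length-at-age about its mean
#'   (dimensionless). Default 0.10.
#' @param t0 Theoretical age at zero length (yr). Default 0.
#' @param lm95 Length at 95\% maturity (cm). Default \code{1.1 * lm50}.
#' @param fec_b Exponent of the fecundity-length power law (eggs proportional
#'   to length^\code{fec_b}). Default 3 (fecundity proportional to weight).
#' @param am Female age at maturity (yr).
#' @param tmax Maximum age (yr); upper limit of all age-structured sums.
#' @param max_len Reported maximum observed length (cm), informational only.
#'
#' @return An object of class \code{"life_history"}: a named list of the
#'   validated (and completed) parameters.
#' @examples
#' lh <- life_history(l_inf = 110, lm50 = 65.3, m_nat = 0.29, m_over_k = 2.7,
#'                    am = 6.5, tmax = 21)
#' lh$k_growth  # derived: 0.29 / 2.7
#' @export
life_history <- function(l_inf, lm50, m_nat = NULL, k_growth = NULL,
                         m_over_k = NULL, cv_linf = 0.10, t0 = 0,
                         lm95 = 1.1 * lm50, fec_b = 3,
                         am = NA_real_, tmax = NA_real_, max_len = NA_real_) {
  stopifnot(is.numeric(l_inf), length(l_inf) == 1L, l_inf > 0)
  n_given <- sum(!vapply(list(m_nat, k_growth, m_over_k), is.null, logical(1)))
  if (n_given < 2L)
    stop("supply at least two of 'm_nat', 'k_growth', 'm_over_k'")
  if (is.null(m_nat))    m_nat    <- k_growth * m_over_k
  if (is.null(k_growth)) k_growth <- m_nat / m_over_k
  if (is.null(m_over_k)) m_over_k <- m_nat / k_growth
  if (abs(m_over_k - m_nat / k_growth) > 1e-9)
    stop("inconsistent mortality/growth parameters: m_over_k != m_nat / k_growth")
  if (m_nat <= 0) stop("'m_nat' must be positive")
  if (k_growth <= 0) stop("'k_growth' must be positive")
  if (!(lm50 > 0 && lm95 > lm50 && lm95 < l_inf))
    stop("need 0 < lm50 < lm95 < l_inf")
  if (cv_linf < 0) stop("'cv_linf' must be nonnegative")
  if (!is.na(am) && !is.na(tmax) && !(am > 0 && am < tmax))
    stop("need 0 < am < tmax")
  structure(
    list(l_inf = l_inf, cv_linf = cv_linf, m_nat = m_nat,
         k_growth = k_growth, m_over_k = m_over_k, t0 = t0,
         lm50 = lm50, lm95 = lm95, fec_b = fec_b,
         am = am, tmax = tmax, max_len = max_len),
    class = "life_history")
}

#' Life history of the Galapagos sailfin grouper (bacalao)
#'
#' Convenience constructor holding the published life-history values for
#' \emph{Mycteroperca olfax}: L-infinity 110 cm, length at maturity 65.3 cm,
#' natural mortality 0.29/yr (from a congener), M/k = 2.7, female age at
#' maturity 6.5 yr, maximum age 21 yr, maximum reported length 120 cm.
#'
#' @param ... Overrides passed on to [life_history()] (e.g. \code{cv_linf}).
#' @return A \code{"life_history"} object.
#' @examples
#' bacalao_life_history()$m_over_k
#' @export
bacalao_life_history <- function(...) {
  args <- list(l_inf = 110, lm50 = 65.3, m_nat = 0.29, m_over_k = 2.7,
               am = 6.5, tmax = 21, max_len = 120)
  override <- list(...)
  args[names(override)] <- override
  do.call(life_history, args)
}

#' @export
print.life_history <- function(x, ...) {
  cat("Life history:\n")
  cat(sprintf("  Linf = %.1f cm (CV %.2f), k = %.4f /yr, t0 = %.2f yr\n",
              x$l_inf, x$cv_linf, x$k_growth, x$t0))
  cat(sprintf("  M = %.3f /yr, M/k = %.2f\n", x$m_nat, x$m_over_k))
  cat(sprintf("  Maturity: Lm50 = %.1f, Lm95 = %.1f cm; fecundity exponent b = %g\n",
              x$lm50, x$lm95, x$fec_b))
  cat(sprintf("  Ages: maturity %.1f yr, maximum %.1f yr\n", x$am, x$tmax))
  invisible(x)
}

#' Mean length at age under von Bertalanffy growth
#'
#' @param age Age(s) in years.
#' @param lh A [life_history()] object.
#' @param l_inf Optional override of the asymptotic length (used by the
#'   growth-type-group machinery, where each group has its own L-infinity).
#' @return Mean total length (cm), floored at 0 for ages below \code{t0}.
#' @export
length_at_age <- function(age, lh, l_inf = lh$l_inf) {
  pmax(0, l_inf * (1 - exp(-lh$k_growth * (age - lh$t0))))
}

#' Read an assessment configuration file
#'
#' Reads a flat YAML file holding life-history values and module defaults and
#' returns the resolved configuration (file values over package defaults).
#' Recognised life-history keys are the arguments of [life_history()]; other
#' keys (e.g. \code{bin_width}, \code{n_gtg}, \code{n_boot}, \code{seed},
#' \code{data}, \code{out_dir}) are kept as-is for the pipeline driver.
#'
#' @param path Path to a YAML configuration file.
#' @return A list with elements \code{life_history} (a built
#'   \code{"life_history"} object) and \code{options} (everything else,
#'   defaults filled in).
#' @seealso [run_assessment()]
#' @export
read_assessment_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  lh_keys <- names(formals(life_history))
  lh_args <- raw[intersect(names(raw), lh_keys)]
  lh <- if (length(lh_args)) do.call(life_history, lh_args)
        else bacalao_life_history()
  opts <- raw[setdiff(names(raw), lh_keys)]
  defaults <- list(bin_width = 2, n_gtg = 13, gtg_sd_range = 2.5,
                   n_boot = 100, trend_boot = 1000, seed = 1,
                   max_tl = 200, limb = "peak")
  for (k in names(defaults)) if (is.null(opts[[k]])) opts[[k]] <- defaults[[k]]
  list(life_history = lh, options = opts)
}
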