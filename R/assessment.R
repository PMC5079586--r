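#' Run the full length-based assessment pipeline
#'
#' Orchestrates ingest, catch-composition indicators, the length-based SPR
#' fit, catch-curve mortality, generational turnover, and year-trend models,
#' collecting every stage's output and a reproducibility manifest (resolved
#' configuration, input digest, seeds, package version, per-stage status).
#' Stage failures are isolated: a failed stage records its error message and
#' downstream stages that depend on it are skipped with a reason.
#'
#' @param config Path to a YAML configuration file (see
#'   [read_assessment_config()]) or an already-resolved config list. The
#'   config either names a \code{data} CSV of per-fish records or a
#'   \code{simulate} block (\code{years}, \code{f_over_m}, \code{sl50},
#'   \code{sl95}, \code{n_per_year}).
#' @param out_dir Optional directory; when given, every table is written as
#'   CSV plus a \code{manifest.yaml}.
#' @return Object of class \code{"assessment_report"}: list with
#'   \code{indicators}, \code{lbspr}, \code{mortality}, \code{turnover},
#'   \code{trends}, \code{validation}, and \code{manifest}.
#' @export
run_assessment <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) read_assessment_config(config) else config
  lh <- cfg$life_history
  opts <- cfg$options
  status <- list()
  note <- function(stage, ok, msg = "") status[[stage]] <<- list(ok = ok, msg = msg)
  res <- list()
  digest <- NA_character_

  # --- ingest -------------------------------------------------------------
  ds <- NULL
  res$validation <- NULL
  if (!is.null(opts$data)) {
    if (!file.exists(opts$data)) stop("input data file not found: ", opts$data)
    digest <- unname(tools::md5sum(opts$data))
    rd <- read_length_records(opts$data,
                              max_tl = opts$max_tl %||% 200)
    ds <- rd$data
    res$validation <- rd$report
    note("ingest", TRUE, sprintf("%d records kept", rd$report$n_kept))
  } else if (!is.null(opts$simulate)) {
    s <- opts$simulate
    scen <- sim_scenario(lh, years = s$years, f_over_m = s$f_over_m,
                         sel = selectivity_params(s$sl50, s$sl95),
                         n_per_year = s$n_per_year,
                         seed = opts$seed)
    ds <- simulate_timeseries(scen)
    note("ingest", TRUE, sprintf("simulated %d records", nrow(ds)))
  } else stop("config must provide either 'data' or a 'simulate' block")

  run_stage <- function(stage, expr) {
    tryCatch({ v <- force(expr); note(stage, TRUE); v },
             error = function(e) { note(stage, FALSE, conditionMessage(e)); NULL })
  }

  # --- indicators ---------------------------------------------------------
  opt <- compute_lopt(lh$l_inf)
  res$optimal_length <- opt
  res$indicators <- run_stage("indicators", compute_indicators(ds, lh, opt))

  # --- LB-SPR on the focal (latest, or configured) year -------------------
  focal <- opts$lbspr_year %||% max(ds$year)
  res$lbspr <- run_stage("lbspr", {
    tl <- ds$tl_cm[ds$year == focal]
    if (length(tl) < 50) warning("focal year has fewer than 50 fish")
    bins <- make_length_bins(lh, width = opts$bin_width)
    fit_lbspr(length_composition(tl, bins), lh,
              n_gtg = opts$n_gtg, sd_range = opts$gtg_sd_range,
              n_boot = opts$n_boot, seed = opts$seed)
  })

  # --- catch curve on the focal year --------------------------------------
  res$mortality <- run_stage("catch_curve", {
    sub <- ds[ds$year == focal, , drop = FALSE]
    chapman_robson(build_age_frequency(sub, lh, limb = opts$limb))
  })
  res$turnover <- run_stage("turnover", generational_turnover(lh$am, lh$tmax))

  # --- trends -------------------------------------------------------------
  res$trends <- run_stage("trends", {
    ind <- res$indicators
    if (is.null(ind) || nrow(ind) < 3L) stop("indicator table unavailable or too short")
    list(
      mature = fit_binomial_trend(round(ind$pct_mature * ind$n / 100),
                                  ind$n, ind$year),
      opt = fit_binomial_trend(round(ind$pct_opt * ind$n / 100),
                               ind$n, ind$year),
      mega = fit_binomial_trend(round(ind$pct_mega * ind$n / 100),
                                ind$n, ind$year),
      mean_tl = if (length(unique(ds$source)) >= 2L) {
        mt <- fit_mixed_trend(ds)
        pb <- parametric_bootstrap_test(ds, n_boot = opts$trend_boot,
                                        seed = opts$seed)
        mt$pb_stat <- pb$pb_stat; mt$pb_p <- pb$pb_p; mt$n_boot <- pb$n_boot
        mt
      } else NULL)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("lenstock")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    input = opts$data %||% "simulated",
    input_md5 = digest,
    seed = opts$seed,
    focal_year = focal,
    life_history = lh[!vapply(lh, is.na, TRUE)],
    options = opts[setdiff(names(opts), "simulate")],
    stages = lapply(status, function(s) if (s$ok) paste("ok", s$msg) else paste("FAILED:", s$msg)))
  res$manifest <- manifest
  out <- structure(res, class = "assessment_report")
  if (!is.null(out_dir)) write_assessment_report(out, out_dir)
  out
}

#' Write an assessment report bundle to disk
#'
#' @param report An [run_assessment()] result.
#' @param out_dir Directory (created if missing).
#' @return \code{out_dir}, invisibly.
#' @export
write_assessment_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$indicators))
    utils::write.csv(report$indicators, file.path(out_dir, "indicators.csv"),
                     row.names = FALSE)
  if (!is.null(report$lbspr)) {
    f <- report$lbspr
    utils::write.csv(
      data.frame(f_over_m = f$f_over_m, sl50 = f$sel$sl50, sl95 = f$sel$sl95,
                 spr = f$spr, loglik = f$loglik, converged = f$converged,
                 sd_f_over_m = f$sd_f_over_m, sd_sl50 = f$sd_sl50,
                 sd_sl95 = f$sd_sl95, sd_spr = f$sd_spr, n_fish = f$n_fish),
      file.path(out_dir, "lbspr_fit.csv"), row.names = FALSE)
  }
  if (!is.null(report$mortality)) {
    m <- report$mortality
    utils::write.csv(
      data.frame(s_annual = m$s_annual, z_total = m$z_total, se_s = m$se_s,
                 se_z = m$se_z, n_used = m$n_used, t_sum = m$t_sum),
      file.path(out_dir, "mortality.csv"), row.names = FALSE)
  }
  if (!is.null(report$trends)) {
    tr <- report$trends
    rows <- do.call(rbind, lapply(c("mature", "opt", "mega"), function(nm) {
      b <- tr[[nm]]
      if (is.null(b)) return(NULL)
      data.frame(indicator = nm, slope = b$slope, lr_chisq = b$lr_chisq,
                 p_value = b$p_value)
    }))
    utils::write.csv(rows, file.path(out_dir, "indicator_trends.csv"),
                     row.names = FALSE)
    if (!is.null(tr$mean_tl)) {
      mt <- tr$mean_tl
      utils::write.csv(
        data.frame(slope_cm_per_yr = mt$slope, slope_se = mt$slope_se,
                   source_sd = mt$source_sd, resid_sd = mt$resid_sd,
                   pb_stat = mt$pb_stat %||% NA, pb_p = mt$pb_p %||% NA),
        file.path(out_dir, "mean_tl_trend.csv"), row.names = FALSE)
    }
  }
  yaml::write_yaml(report$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' @export
print.assessment_report <- function(x, ...) {
  cat("=== Length-based stock assessment report ===\n\n")
  print(x$optimal_length)
  if (!is.null(x$indicators)) {
    cat("\nPer-year indicators:\n")
    ind <- x$indicators
    ind[3:7] <- lapply(ind[3:7], round, 1)
    print(ind, row.names = FALSE)
  }
  if (!is.null(x$lbspr)) { cat("\n"); print(x$lbspr) }
  if (!is.null(x$mortality)) { cat("\n"); print(x$mortality) }
  if (!is.null(x$turnover)) { cat("\n"); print(x$turnover) }
  if (!is.null(x$trends)) {
    cat("\nYear trends:\n")
    for (nm in c("mature", "opt", "mega")) {
      b <- x$trends[[nm]]
      if (!is.null(b))
        cat(sprintf("  %% %s: LR chi-sq = %.2f, p = %.3g\n",
                    c(mature = "mature", opt = "in optimum interval",
                      mega = "mega-spawners")[[nm]], b$lr_chisq, b$p_value))
    }
    mt <- x$trends$mean_tl
    if (!is.null(mt))
      cat(sprintf("  mean TL: %.3f cm/yr (se %.3f), PB stat = %.1f, p = %.3g\n",
                  mt$slope, mt$slope_se, mt$pb_stat %||% NA, mt$pb_p %||% NA))
  }
  cat("\nStages:", paste(names(x$manifest$stages), collapse = ", "), "\n")
  invisible(x)
}
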