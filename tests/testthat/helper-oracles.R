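# Independent brute-force oracle for the single-group per-recruit
# observation model: explicit scalar loops, formulas written out inline --
# shares no code path with the package implementation.
oracle_composition <- function(lh, f_over_m, sl50, sl95, edges) {
  ages <- 0:lh$tmax
  la <- lh$l_inf * (1 - exp(-lh$k_growth * (ages - lh$t0)))
  la[la < 0] <- 0
  sel_fun <- function(l) 1 / (1 + exp(-log(19) * (l - sl50) / (sl95 - sl50)))
  n_at_age <- numeric(length(ages))
  n_at_age[1] <- 1
  for (a in seq_along(ages)[-1]) {
    z_prev <- lh$m_nat + f_over_m * lh$m_nat * sel_fun(la[a - 1])
    n_at_age[a] <- n_at_age[a - 1] * exp(-z_prev)
  }
  nb <- length(edges) - 1
  catch <- numeric(nb)
  for (b in seq_len(nb)) {
    mid <- (edges[b] + edges[b + 1]) / 2
    for (a in seq_along(ages)) {
      p <- pnorm(edges[b + 1], la[a], lh$cv_linf * la[a]) -
           pnorm(edges[b], la[a], lh$cv_linf * la[a])
      catch[b] <- catch[b] + n_at_age[a] * p * sel_fun(mid)
    }
  }
  catch / sum(catch)
}

# Independent Newton-Raphson oracle for the binomial logistic year trend.
oracle_logistic <- function(successes, totals, years) {
  X <- cbind(1, years - mean(years))
  beta <- c(0, 0)
  for (it in 1:100) {
    p <- 1 / (1 + exp(-drop(X %*% beta)))
    grad <- drop(t(X) %*% (successes - totals * p))
    H <- t(X) %*% (totals * p * (1 - p) * X)
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < 1e-12) break
  }
  p <- 1 / (1 + exp(-drop(X %*% beta)))
  p0 <- sum(successes) / sum(totals)
  ll <- function(pr) sum(successes * log(pr) + (totals - successes) * log(1 - pr))
  list(beta = beta, lr = 2 * (ll(p) - ll(rep(p0, length(p)))))
}
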