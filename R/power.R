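#' Power frameworks for paired differences and survival associations
#'
#' Two complementary frameworks quantify what effect sizes the cohort can
#' detect, which is what makes null results interpretable. For paired
#' tumor-normal comparisons, the noncentrality parameter of the paired
#' t-test is `xi = beta * sqrt(n)` with standardized effect
#' `beta = E(delta)/sigma`, and the power of the two-sided level-alpha test
#' is approximated by the normal distribution as
#' `Phi(xi - C_alpha) + Phi(-xi - C_alpha)` with
#' `C_alpha = qnorm(1 - alpha/2)`. For survival, power is estimated by
#' simulation: a log-normal baseline is fitted to the observed follow-up by
#' censored maximum likelihood, event times are generated from the
#' proportional-hazards model by inverse-probability sampling
#' (`T = S0^-1(U^exp(-beta z))`), a random fraction of subjects is
#' censored, and a Cox model's Wald test is applied; power is the fraction
#' of simulations rejecting.
#'
#' @name power
NULL

#' Analytic power of the paired test (normal approximation)
#'
#' `power = Phi(beta*sqrt(n) - C_alpha) + Phi(-beta*sqrt(n) - C_alpha)`;
#' both terms are retained, so at `beta = 0` the formula returns exactly
#' `alpha`.
#'
#' @param beta standardized effect `E(delta)/sigma`.
#' @param n number of paired subjects (>= 2).
#' @param alpha two-sided significance level.
#' @return power in \[0, 1\]; vectorized over `beta`.
#' @export
paired_power <- function(beta, n, alpha) {
  stopifnot(n >= 2, alpha > 0, alpha < 1)
  c_alpha <- stats::qnorm(1 - alpha / 2)
  xi <- beta * sqrt(n)
  stats::pnorm(xi - c_alpha) + stats::pnorm(-xi - c_alpha)
}

#' Minimum standardized effect detectable at a target power
#'
#' Solves `paired_power(beta, n, alpha) = power_target` for `beta >= 0`.
#' The closed form `(qnorm(1-alpha/2) + qnorm(power)) / sqrt(n)` (which
#' drops the negligible second term) seeds a bisection refined to `tol`.
#'
#' @param n paired subjects.
#' @param alpha two-sided level.
#' @param power_target target power (default 0.80).
#' @param tol solution tolerance on beta (default 1e-6).
#' @return minimum detectable standardized effect.
#' @export
min_detectable_effect <- function(n, alpha, power_target = 0.80, tol = 1e-6) {
  stopifnot(power_target > alpha, power_target < 1)
  seed_beta <- (stats::qnorm(1 - alpha / 2) + stats::qnorm(power_target)) / sqrt(n)
  lo <- 0
  hi <- max(2 * seed_beta, 1e-3)
  while (paired_power(hi, n, alpha) < power_target) hi <- hi * 2
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (paired_power(mid, n, alpha) < power_target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Censored maximum-likelihood fit of a log-normal survival distribution
#'
#' Fits `log T ~ N(mu, sigma^2)` to right-censored follow-up: density terms
#' for events, survival terms for censored subjects (via
#' `survival::survreg(dist = "lognormal")`). With
#' `use_censored = FALSE` only events enter, as a sensitivity option.
#'
#' @param times positive follow-up times.
#' @param events 1 = death, 0 = censored.
#' @param use_censored include censored subjects via survival terms
#'   (default TRUE).
#' @return list: mu, sigma, n, n_events, degenerate (TRUE when sigma
#'   collapses toward 0).
#' @export
fit_lognormal_survival <- function(times, events, use_censored = TRUE) {
  stopifnot(length(times) == length(events), all(times > 0))
  if (sum(events) < 2)
    stop_lowbiome("need at least 2 events", class = "lowbiome_validation_error")
  if (!use_censored || all(events == 1)) {
    # event-only ML has the closed form (and equals the full ML when
    # nothing is censored); also robust when the log-times are constant
    lt <- log(times[events == 1])
    mu <- mean(lt)
    sigma <- sqrt(mean((lt - mu)^2))  # ML (1/n) variance
  } else {
    fit <- suppressWarnings(
      survival::survreg(survival::Surv(times, events) ~ 1,
                        dist = "lognormal"))
    mu <- unname(stats::coef(fit)[1])
    sigma <- fit$scale
  }
  degenerate <- sigma < 1e-8
  if (degenerate) warning("sigma collapsed to ~0: degenerate fit")
  list(mu = mu, sigma = sigma, n = length(times), n_events = sum(events),
       degenerate = degenerate)
}

#' Generate proportional-hazards event times over a log-normal baseline
#'
#' Inverse-probability sampling: with baseline survival
#' `S0(t) = 1 - Phi((ln t - mu)/sigma)` and `U ~ Uniform(0,1)`,
#' `T = S0^-1(U^exp(-beta z))` follows the PH model
#' `H(t|z) = H0(t) exp(beta z)`.
#'
#' @param n number of subjects (ignored when `u` is supplied).
#' @param z covariate values (length n).
#' @param beta log hazard ratio per unit of z.
#' @param mu,sigma log-normal baseline parameters.
#' @param u optional uniforms (for deterministic evaluation / common random
#'   numbers); drawn internally otherwise.
#' @return event times (length n).
#' @export
simulate_event_times <- function(n = length(z), z, beta, mu, sigma, u = NULL) {
  stopifnot(sigma > 0, length(z) == n)
  if (is.null(u)) u <- stats::runif(n)
  # log S = exp(-beta z) * log U, kept on the log scale so extreme hazards
  # do not underflow S to 0 (which would give infinite event times)
  log_s <- exp(-beta * z) * log(u)
  exp(mu + sigma * stats::qnorm(log_s, lower.tail = FALSE, log.p = TRUE))
}

#' Simulation-based power of the per-taxon Cox test
#'
#' Each replicate draws a standard-normal microbiome feature `z` for `n`
#' subjects, generates PH event times over the log-normal baseline,
#' censors a random `censor_fraction` of subjects (each at a uniform time
#' on `(0, T_i)` by default; `censoring = "admin"` instead censors at the
#' baseline quantile matching the fraction), fits a Cox model, and records
#' the Wald p-value for `beta = 0`. Power is the rejection fraction at
#' `alpha`.
#'
#' @param beta log hazard ratio under the alternative.
#' @param n subjects per replicate.
#' @param mu,sigma log-normal baseline parameters.
#' @param censor_fraction fraction of subjects censored, in \[0, 1).
#' @param alpha rejection threshold on the Wald p-value.
#' @param n_sims replicates (default 1000).
#' @param seed RNG seed.
#' @param censoring `"random"` (default) or `"admin"`.
#' @return list: power, mc_se (binomial Monte-Carlo standard error),
#'   rejections, n_sims, n_failed.
#' @export
survival_power_sim <- function(beta, n, mu, sigma, censor_fraction = 0,
                               alpha = 0.05, n_sims = 1000, seed = 1L,
                               censoring = c("random", "admin")) {
  censoring <- match.arg(censoring)
  stopifnot(censor_fraction >= 0, censor_fraction < 1, n_sims >= 1)
  with_seed(seed, {
    pvals <- rep(NA_real_, n_sims)
    for (s in seq_len(n_sims)) {
      z <- stats::rnorm(n)
      t_event <- simulate_event_times(n, z, beta, mu, sigma)
      event <- rep(1L, n)
      time <- t_event
      if (censor_fraction > 0) {
        n_cens <- round(censor_fraction * n)
        idx <- sample.int(n, n_cens)
        if (censoring == "random") {
          time[idx] <- stats::runif(n_cens, 0, t_event[idx])
        } else {
          tc <- exp(mu + sigma * stats::qnorm(1 - censor_fraction))
          time[idx] <- pmin(t_event[idx], tc)
        }
        event[idx] <- ifelse(time[idx] < t_event[idx], 0L, event[idx])
        if (censoring == "random") event[idx] <- 0L
      }
      # timefix would merge exact simulated times spanning many orders of
      # magnitude into spurious ties; these times carry no measurement fuzz
      fit <- tryCatch(
        suppressWarnings(
          survival::coxph(survival::Surv(time, event) ~ z, ties = "breslow",
                          control = survival::coxph.control(timefix = FALSE))),
        error = function(e) NULL)
      if (is.null(fit)) next
      co <- summary(fit)$coefficients
      pvals[s] <- co[1, "Pr(>|z|)"]
    }
    failed <- sum(is.na(pvals))
    if (failed > 0.05 * n_sims)
      stop_lowbiome("more than 5% of replicates failed to fit",
                    class = "lowbiome_simulation_error")
    ok <- !is.na(pvals)
    p_hat <- mean(pvals[ok] < alpha)
    list(power = p_hat,
         mc_se = sqrt(p_hat * (1 - p_hat) / sum(ok)),
         rejections = sum(pvals[ok] < alpha),
         n_sims = sum(ok),
         n_failed = failed)
  })
}

#' Schoenfeld closed-form power approximation for the Cox test
#'
#' `power = Phi(|beta| * sqrt(D) - z_{1-alpha/2})` with `D` the expected
#' number of events and unit-variance covariate. Used as an independent
#' cross-check of [survival_power_sim()] in uncensored configurations.
#'
#' @param beta log hazard ratio.
#' @param d_events expected number of events.
#' @param alpha two-sided level.
#' @return approximate power.
#' @export
schoenfeld_power <- function(beta, d_events, alpha = 0.05) {
  stats::pnorm(abs(beta) * sqrt(d_events) - stats::qnorm(1 - alpha / 2))
}

#' Minimum detectable hazard ratio at a target power
#'
#' Bisection on the log hazard ratio over [survival_power_sim()], using
#' common random numbers (the same seed at every bisection step) so the
#' estimated power curve is monotone in beta within a run. Because the
#' feature is symmetric standard normal, the minimum protective hazard
#' ratio is the reciprocal of the returned value.
#'
#' @param n,mu,sigma,censor_fraction,alpha,n_sims,seed as in
#'   [survival_power_sim()].
#' @param power_target target power (default 0.80).
#' @param tol bisection tolerance on the log hazard ratio (default 0.01).
#' @param beta_max initial upper bracket on |beta| (doubled if needed).
#' @return list: hr, log_hr, power_at_solution.
#' @export
min_detectable_hr <- function(n, mu, sigma, censor_fraction = 0,
                              alpha = 0.05, n_sims = 200, seed = 1L,
                              power_target = 0.80, tol = 0.01,
                              beta_max = 1) {
  pw <- function(b) survival_power_sim(b, n, mu, sigma, censor_fraction,
                                       alpha, n_sims, seed)$power
  lo <- 0
  hi <- beta_max
  tries <- 0
  while (pw(hi) < power_target) {
    hi <- hi * 2
    tries <- tries + 1
    if (tries > 10)
      stop_lowbiome("failed to bracket the target power",
                    class = "lowbiome_simulation_error")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (pw(mid) < power_target) lo <- mid else hi <- mid
  }
  # report the verified upper bracket: under common random numbers its
  # estimated power is >= the target by construction
  list(hr = exp(hi), log_hr = hi, power_at_solution = pw(hi))
}
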