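# Estimators of the absolute AE probability P(AE in [0, tau]) in one arm.
#
# All five estimators consume subject-level first-event records and return a
# one-row tibble in a common shape, so arm-wise results stack into the
# aggregated-summary schema. Step-function estimators additionally carry the
# full curve as an attribute (see risk_curve()).

RISK_ESTIMATORS <- c("ip", "id", "id_ce", "one_minus_km", "aje")

# Per-time-point event table: unique sorted observation times with the risk
# set and the AE / competing-event / censoring counts at each. Ties between
# events and censorings at the same time are handled by processing events
# first: the risk set at t contains every subject with time >= t, and is
# decremented only after the time point.
event_table <- function(records) {
  times <- sort(unique(records$time))
  sorted_all <- sort(records$time)
  count_at <- function(code) {
    tabulate(
      match(records$time[records$event_code == code], times),
      nbins = length(times)
    )
  }
  tibble::tibble(
    time = times,
    # subjects with time >= t (left-open interval count of strictly smaller times)
    n_risk = length(sorted_all) - findInterval(times, sorted_all, left.open = TRUE),
    d_ae = count_at(EVENT_AE),
    d_ce = count_at(EVENT_CE),
    n_cens = count_at(EVENT_CENSORED)
  )
}

# Counts entering the aggregated schema, all restricted to [0, tau].
risk_components <- function(records, tau) {
  tibble::tibble(
    n = nrow(records),
    d_ae = sum(records$event_code == EVENT_AE & records$time <= tau),
    d_ce = sum(records$event_code == EVENT_CE & records$time <= tau),
    n_cens = sum(records$event_code == EVENT_CENSORED & records$time <= tau),
    person_time = sum(pmin(records$time, tau))
  )
}

new_risk_estimate <- function(estimator, arm, tau, estimate, variance, comps,
                              tau_beyond_data, curve = NULL) {
  out <- dplyr::bind_cols(
    tibble::tibble(
      estimator = estimator, arm = arm, tau = tau,
      estimate = estimate, variance = variance
    ),
    comps,
    tibble::tibble(tau_beyond_data = tau_beyond_data)
  )
  class(out) <- c("risk_estimate", class(out))
  attr(out, "curve") <- curve
  out
}

check_tau <- function(tau, records) {
  if (!is.numeric(tau) || length(tau) != 1 || !is.finite(tau) || tau <= 0) {
    abort("`tau` must be a single positive finite number.")
  }
  tau > max(records$time)
}

#' Incidence proportion
#'
#' The number of subjects with an observed AE in \eqn{[0, \tau]} divided by
#' the number of subjects in the arm. It estimates the probability that an AE
#' happens in \eqn{[0, \tau]} *and* is observed: censoring is ignored, while
#' competing events are accounted for correctly. Variance is binomial,
#' \eqn{\hat q(1-\hat q)/n}.
#'
#' @param data A [trial_data] tibble (or any data frame with `time`,
#'   `event_code` and `arm` columns).
#' @param arm Arm label to estimate in; may be omitted for single-arm data.
#' @param tau Evaluation time; defaults to the pooled maximal evaluation time
#'   of `data`.
#' @return A one-row `risk_estimate` tibble with columns `estimator`, `arm`,
#'   `tau`, `estimate`, `variance`, the event counts, and a
#'   `tau_beyond_data` flag set when `tau` exceeds the largest observed time.
#' @export
incidence_proportion <- function(data, arm = NULL, tau = max_eval_time(data)) {
  records <- arm_records(data, arm)
  beyond <- check_tau(tau, records)
  comps <- risk_components(records, tau)
  p <- comps$d_ae / comps$n
  new_risk_estimate(
    "ip", records$arm[1], tau, p, p * (1 - p) / comps$n, comps, beyond
  )
}

#' Incidence density (rate) of an event type
#'
#' Events of the given type in \eqn{[0, \tau]} divided by the total
#' person-time at risk \eqn{\sum_i \min(t_i, \tau)}. This is a constant-hazard
#' (exponential) estimator of the event-specific hazard, not of a
#' probability; see [prob_transform_id()] for the probability transform.
#' Variance treats the event count as Poisson with fixed person-time:
#' \eqn{D / PT^2}.
#'
#' @inheritParams incidence_proportion
#' @param event `"ae"` or `"ce"`.
#' @return A one-row tibble with `rate`, `rate_variance`, `events`,
#'   `person_time`.
#' @export
incidence_density <- function(data, arm = NULL, tau = max_eval_time(data),
                              event = c("ae", "ce")) {
  event <- rlang::arg_match(event)
  records <- arm_records(data, arm)
  check_tau(tau, records)
  comps <- risk_components(records, tau)
  if (comps$person_time <= 0) {
    abort("Zero person-time at risk; incidence density is undefined.")
  }
  d <- if (event == "ae") comps$d_ae else comps$d_ce
  tibble::tibble(
    event = event, arm = records$arm[1], tau = tau,
    rate = d / comps$person_time,
    rate_variance = d / comps$person_time^2,
    events = d, person_time = comps$person_time
  )
}

#' Probability transform of the incidence density (ignoring competing events)
#'
#' Converts the AE incidence density \eqn{\hat\lambda} into a probability
#' under a constant-hazard model: \eqn{1 - \exp(-\hat\lambda \tau)}. Fully
#' parametric; accounts for varying follow-up but not for competing events,
#' so it targets the wrong quantity whenever competing hazards are present.
#' Variance by the delta method from the Poisson variance of the rate.
#'
#' @inheritParams incidence_proportion
#' @export
prob_transform_id <- function(data, arm = NULL, tau = max_eval_time(data)) {
  records <- arm_records(data, arm)
  beyond <- check_tau(tau, records)
  comps <- risk_components(records, tau)
  if (comps$person_time <= 0) {
    abort("Zero person-time at risk; incidence density is undefined.")
  }
  lambda <- comps$d_ae / comps$person_time
  p <- 1 - exp(-lambda * tau)
  grad <- tau * exp(-lambda * tau)
  v <- grad^2 * comps$d_ae / comps$person_time^2
  new_risk_estimate("id", records$arm[1], tau, p, v, comps, beyond)
}

#' Probability transform of incidence densities accounting for competing
#' events
#'
#' With AE and competing-event incidence densities \eqn{a} and \eqn{b}, the
#' constant-hazards competing-risks model gives the AE probability
#' \deqn{\frac{a}{a+b}\bigl(1 - e^{-(a+b)\tau}\bigr),}
#' defined as 0 when \eqn{a + b = 0}. This keeps the parametric
#' constant-hazard assumption but accounts for competing events. Variance by
#' the delta method treating the AE and CE counts as independent Poisson.
#'
#' @inheritParams incidence_proportion
#' @export
prob_transform_id_ce <- function(data, arm = NULL, tau = max_eval_time(data)) {
  records <- arm_records(data, arm)
  beyond <- check_tau(tau, records)
  comps <- risk_components(records, tau)
  if (comps$person_time <= 0) {
    abort("Zero person-time at risk; incidence density is undefined.")
  }
  pt <- comps$person_time
  a <- comps$d_ae / pt
  b <- comps$d_ce / pt
  s <- a + b
  if (s == 0) {
    p <- 0
    v <- 0
  } else {
    f <- 1 - exp(-s * tau)
    p <- a / s * f
    # gradient of a/s * (1 - exp(-s tau)) w.r.t. (a, b)
    common <- a * (tau * exp(-s * tau) * s - f) / s^2
    da <- f / s + common
    db <- common
    v <- da^2 * comps$d_ae / pt^2 + db^2 * comps$d_ce / pt^2
  }
  new_risk_estimate("id_ce", records$arm[1], tau, p, v, comps, beyond)
}

# Product-limit machinery shared by one_minus_km and aalen_johansen. Returns
# the event table augmented with the all-cause survival S(t), its left limit,
# both cumulative incidence functions, and the AE-only Kaplan-Meier.
product_limit_table <- function(records) {
  tab <- event_table(records)
  d_all <- tab$d_ae + tab$d_ce
  surv_all <- cumprod(1 - d_all / tab$n_risk)
  surv_minus <- dplyr::lag(surv_all, default = 1)
  km_ae <- cumprod(1 - tab$d_ae / tab$n_risk)
  # Greenwood for the AE-only product limit (CE and censoring both censored)
  green_incr <- ifelse(tab$n_risk > tab$d_ae,
    tab$d_ae / (tab$n_risk * (tab$n_risk - tab$d_ae)), 0
  )
  km_var <- km_ae^2 * cumsum(green_incr)
  # at the time S hits zero Greenwood is degenerate; variance 0 there
  km_var[km_ae == 0] <- 0
  dplyr::mutate(tab,
    d_all = d_all, surv_all = surv_all, surv_minus = surv_minus,
    cif_ae = cumsum(surv_minus * .data$d_ae / .data$n_risk),
    cif_ce = cumsum(surv_minus * .data$d_ce / .data$n_risk),
    km_ae = km_ae, km_ae_var = km_var
  )
}

# Aalen-type (counting-process) variance of the cumulative incidence of one
# event type, evaluated at each event time of the table. For CIF F_e at time
# t, with all-cause events d_j and cause-specific events d_ej at t_j <= t:
#   Var(t) = sum_j [F(t)-F(t_j)]^2 d_j / (n_j (n_j - d_j))
#          + sum_j S(t_j-)^2 (n_j - d_ej)/n_j * d_ej / n_j^2
#          - 2 sum_j [F(t)-F(t_j)] S(t_j-) d_ej / n_j^2
# Terms with n_j == d_j contribute nothing beyond t_j (S is 0 there), and the
# degenerate Greenwood factor is set to 0.
aje_variance <- function(tab, event) {
  f <- if (event == "ae") tab$cif_ae else tab$cif_ce
  d_e <- if (event == "ae") tab$d_ae else tab$d_ce
  g <- ifelse(tab$n_risk > tab$d_all,
    tab$d_all / (tab$n_risk * (tab$n_risk - tab$d_all)), 0
  )
  t1 <- g
  t2 <- tab$surv_minus^2 * (tab$n_risk - d_e) / tab$n_risk * d_e / tab$n_risk^2
  t3 <- tab$surv_minus * d_e / tab$n_risk^2
  # expand the double sums into cumulative forms (O(#times) instead of O(#times^2))
  f^2 * cumsum(t1) - 2 * f * cumsum(f * t1) + cumsum(f^2 * t1) +
    cumsum(t2) - 2 * (f * cumsum(t3) - cumsum(f * t3))
}

new_step_curve <- function(tab, estimate, variance, estimator, arm, tau) {
  keep <- tab$time <= tau & (tab$d_ae + tab$d_ce) > 0
  out <- tibble::tibble(
    time = tab$time[keep], estimate = estimate[keep],
    variance = pmax(variance[keep], 0),
    n_risk = tab$n_risk[keep], d_ae = tab$d_ae[keep], d_ce = tab$d_ce[keep]
  )
  structure(out,
    class = c("step_curve", class(out)),
    estimator = estimator, arm = arm, tau = tau
  )
}

#' One minus Kaplan-Meier
#'
#' Treats time-to-AE as the endpoint and both competing events and
#' censorings identically as censored, then reads one minus the product-limit
#' estimator off at \eqn{\tau}. Accounts for varying follow-up and censoring,
#' but in the presence of competing events it targets a distribution function
#' that tends to one, so it is biased upwards for the AE probability.
#' Variance by Greenwood's formula.
#'
#' @inheritParams incidence_proportion
#' @return A one-row `risk_estimate`; the full step curve over event times up
#'   to `tau` is available via [risk_curve()].
#' @export
one_minus_km <- function(data, arm = NULL, tau = max_eval_time(data)) {
  records <- arm_records(data, arm)
  beyond <- check_tau(tau, records)
  comps <- risk_components(records, tau)
  tab <- product_limit_table(records)
  est_all <- 1 - tab$km_ae
  curve <- new_step_curve(
    tab[tab$d_ae > 0, ], (1 - tab$km_ae)[tab$d_ae > 0],
    tab$km_ae_var[tab$d_ae > 0], "one_minus_km", records$arm[1], tau
  )
  at <- step_lookup(tab$time, est_all, tau)
  v <- step_lookup(tab$time, tab$km_ae_var, tau)
  new_risk_estimate(
    "one_minus_km", records$arm[1], tau, at, v, comps, beyond, curve
  )
}

#' Aalen-Johansen estimator of the cumulative incidence
#'
#' The nonparametric gold standard: accounts for (random or independent)
#' censoring, varying follow-up times, and competing events simultaneously,
#' with no parametric assumption. The cumulative incidence of the event type
#' is \deqn{\hat F_e(\tau) = \sum_{t_i \le \tau} \hat S(t_i-)\, d_{e,i}/n_i,}
#' with \eqn{\hat S} the all-cause product-limit survival and \eqn{n_i} the
#' risk set. Pointwise variance by a counting-process (Aalen-type) estimator.
#'
#' @inheritParams incidence_density
#' @return A one-row `risk_estimate`; the step curve (with the all-cause
#'   survival in attribute columns) via [risk_curve()].
#' @export
aalen_johansen <- function(data, arm = NULL, tau = max_eval_time(data),
                           event = c("ae", "ce")) {
  event <- rlang::arg_match(event)
  records <- arm_records(data, arm)
  beyond <- check_tau(tau, records)
  comps <- risk_components(records, tau)
  tab <- product_limit_table(records)
  f <- if (event == "ae") tab$cif_ae else tab$cif_ce
  v <- aje_variance(tab, event)
  curve <- new_step_curve(tab, f, v, paste0("aje_", event), records$arm[1], tau)
  curve$surv_all <- tab$surv_all[tab$time <= tau & tab$d_all > 0]
  est_name <- if (event == "ae") "aje" else "aje_ce"
  new_risk_estimate(
    est_name, records$arm[1], tau,
    step_lookup(tab$time, f, tau), max(step_lookup(tab$time, v, tau), 0),
    comps, beyond, curve
  )
}

# Right-continuous step lookup with last value carried forward and 0 before
# the first jump.
step_lookup <- function(times, values, at) {
  idx <- findInterval(at, times)
  ifelse(idx == 0, 0, values[pmax(idx, 1)])
}

#' Extract the step curve underlying a risk estimate
#'
#' @param x A `risk_estimate` produced by [one_minus_km()] or
#'   [aalen_johansen()].
#' @return A `step_curve` tibble (time, estimate, variance, risk set, event
#'   counts), right-continuous with the last value carried forward.
#' @export
risk_curve <- function(x) {
  curve <- attr(x, "curve")
  if (is.null(curve)) {
    abort("This estimate carries no step curve (only the product-limit estimators do).")
  }
  curve
}

#' Evaluate a step curve at arbitrary times
#'
#' @param curve A `step_curve`.
#' @param at Numeric vector of times.
#' @return Numeric vector of curve values (0 before the first jump, last
#'   value carried forward).
#' @export
curve_value <- function(curve, at) {
  vapply(at, function(t) step_lookup(curve$time, curve$estimate, t), numeric(1))
}

#' All five absolute-risk estimators at once
#'
#' Runs the requested estimators in every arm of the dataset at a common
#' evaluation time and stacks the results, ready for [as_aggregate()].
#'
#' @inheritParams incidence_proportion
#' @param estimators Subset of `c("ip", "id", "id_ce", "one_minus_km",
#'   "aje")`.
#' @param ci_level If non-`NULL`, append Wald confidence limits on the
#'   complementary log-log scale (clipped to \[0, 1\]) at this level.
#' @return A tibble with one row per arm and estimator.
#' @examples
#' cfg <- scenario_config(n_per_arm = 100, alpha_e = 0.2, alpha_c = 0.1,
#'                        beta_e = 0.3, beta_c = 0.3, gamma = 0.1, seed = 7)
#' trial <- simulate_trial(cfg)
#' estimate_ae_risk(trial, ci_level = 0.95)
#' @export
estimate_ae_risk <- function(data, tau = max_eval_time(data),
                             estimators = RISK_ESTIMATORS, ci_level = NULL) {
  estimators <- match.arg(estimators, RISK_ESTIMATORS, several.ok = TRUE)
  fns <- list(
    ip = incidence_proportion, id = prob_transform_id,
    id_ce = prob_transform_id_ce, one_minus_km = one_minus_km,
    aje = aalen_johansen
  )
  out <- purrr::map_dfr(sort(unique(data$arm)), function(a) {
    purrr::map_dfr(estimators, function(e) {
      est <- fns[[e]](data, arm = a, tau = tau)
      attr(est, "curve") <- NULL
      class(est) <- setdiff(class(est), "risk_estimate")
      est
    })
  })
  if (!is.null(ci_level)) {
    out <- dplyr::bind_cols(
      out, cloglog_ci(out$estimate, out$variance, ci_level)
    )
  }
  structure(out, trial_id = trial_id(data), ae_id = ae_id(data))
}

# Wald CI for a probability on the complementary log-log scale, clipped to
# [0, 1]. Degenerate at 0 and 1.
cloglog_ci <- function(p, variance, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  se <- sqrt(pmax(variance, 0))
  inner <- p > 0 & p < 1 & se > 0
  lower <- p
  upper <- p
  theta <- log(-log(1 - p[inner]))
  se_theta <- se[inner] / ((1 - p[inner]) * abs(log(1 - p[inner])))
  lower[inner] <- 1 - exp(-exp(theta - z * se_theta))
  upper[inner] <- 1 - exp(-exp(theta + z * se_theta))
  tibble::tibble(
    lower = pmin(pmax(lower, 0), 1),
    upper = pmin(pmax(upper, 0), 1),
    level = level
  )
}
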