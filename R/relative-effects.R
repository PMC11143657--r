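# Between-arm effect estimators: risk ratios per basis estimator,
# incidence-density ratios, and cause-specific Cox hazard ratios, plus the
# bootstrap ratio of a comparator effect to its gold standard.

RR_BASES <- c("aje", "ip", "id", "id_ce", "one_minus_km")

new_relative_effect <- function(measure, basis, tau, estimate, lower, upper,
                                level, log_variance, defined,
                                diverged = FALSE) {
  out <- tibble::tibble(
    measure = measure, basis = basis, tau = tau, estimate = estimate,
    lower = lower, upper = upper, level = level,
    log_variance = log_variance, defined = defined, diverged = diverged
  )
  class(out) <- c("relative_effect", class(out))
  out
}

#' Risk ratio of arm-wise AE probabilities
#'
#' \eqn{\widehat{RR} = \hat q_E / \hat q_C} with the arm-wise AE
#' probabilities \eqn{\hat q} computed by the chosen basis estimator at the
#' evaluation time. The variance on the log scale follows the delta rule,
#' \eqn{\mathrm{Var}(\log \widehat{RR}) = \mathrm{Var}(\hat q_E)/\hat q_E^2 +
#' \mathrm{Var}(\hat q_C)/\hat q_C^2}, with a Wald interval on the log
#' scale. When either arm-wise probability is 0 the effect is flagged
#' `defined = FALSE` (no error), mirroring the exclusion of such AEs from
#' comparative summaries.
#'
#' @inheritParams incidence_proportion
#' @param basis Which absolute-risk estimator supplies the arm-wise
#'   probabilities: `"aje"` (the gold standard), `"ip"`, `"id"`, `"id_ce"`,
#'   or `"one_minus_km"`.
#' @param level Confidence level.
#' @param experimental,control Arm labels; resolved automatically when the
#'   arms are named `"experimental"`/`"control"` or there are exactly two.
#' @return A one-row `relative_effect` tibble.
#' @export
risk_ratio <- function(data, basis = "aje", tau = max_eval_time(data),
                       level = 0.95, experimental = NULL, control = NULL) {
  basis <- rlang::arg_match(basis, RR_BASES)
  arms <- comparison_arms(data, experimental, control)
  fn <- switch(basis,
    aje = aalen_johansen, ip = incidence_proportion, id = prob_transform_id,
    id_ce = prob_transform_id_ce, one_minus_km = one_minus_km
  )
  e <- fn(data, arm = arms[["experimental"]], tau = tau)
  c_ <- fn(data, arm = arms[["control"]], tau = tau)
  if (e$estimate <= 0 || c_$estimate <= 0) {
    return(new_relative_effect(
      "rr", basis, tau, NA_real_, NA_real_, NA_real_, level, NA_real_, FALSE
    ))
  }
  point <- e$estimate / c_$estimate
  log_var <- e$variance / e$estimate^2 + c_$variance / c_$estimate^2
  z <- qnorm(1 - (1 - level) / 2)
  new_relative_effect(
    "rr", basis, tau, point,
    exp(log(point) - z * sqrt(log_var)), exp(log(point) + z * sqrt(log_var)),
    level, log_var, TRUE
  )
}

#' Incidence-density ratio
#'
#' Ratio of the arm-wise incidence densities (rates) of an event type — a
#' hazard-ratio estimator that assumes the event-specific hazards are
#' constant (hence proportional) up to the follow-up time. Wald interval on
#' the log scale with \eqn{\mathrm{Var}(\log) = 1/D_E + 1/D_C} from Poisson
#' event counts. Zero events in either arm give `defined = FALSE`.
#'
#' @inheritParams risk_ratio
#' @param event `"ae"` or `"ce"`.
#' @export
incidence_density_ratio <- function(data, event = c("ae", "ce"),
                                    tau = max_eval_time(data), level = 0.95,
                                    experimental = NULL, control = NULL) {
  event <- rlang::arg_match(event)
  arms <- comparison_arms(data, experimental, control)
  measure <- paste0("idr_", event)
  e <- incidence_density(data, arms[["experimental"]], tau, event)
  c_ <- incidence_density(data, arms[["control"]], tau, event)
  if (e$events == 0 || c_$events == 0) {
    return(new_relative_effect(
      measure, "id", tau, NA_real_, NA_real_, NA_real_, level, NA_real_, FALSE
    ))
  }
  point <- e$rate / c_$rate
  log_var <- 1 / e$events + 1 / c_$events
  z <- qnorm(1 - (1 - level) / 2)
  new_relative_effect(
    measure, "id", tau, point,
    exp(log(point) - z * sqrt(log_var)), exp(log(point) + z * sqrt(log_var)),
    level, log_var, TRUE
  )
}

#' Two-group cause-specific Cox model
#'
#' Fits the cause-specific proportional-hazards model for one event type
#' (the other event type and censoring are treated as censored) with a
#' single binary covariate for treatment arm. The partial likelihood uses
#' Breslow tie handling and is maximized by Newton-Raphson (tolerance 1e-8,
#' at most 50 iterations, with step halving). With all events of the type in
#' one arm the partial likelihood is monotone and the estimate diverges;
#' this is flagged rather than iterated into overflow.
#'
#' @inheritParams incidence_density_ratio
#' @return An object of class `aerisk_cox` with [tidy()] and [glance()]
#'   methods.
#' @export
fit_cause_specific_cox <- function(data, event = c("ae", "ce"),
                                   experimental = NULL, control = NULL) {
  event <- rlang::arg_match(event)
  arms <- comparison_arms(data, experimental, control)
  code <- if (event == "ae") EVENT_AE else EVENT_CE
  keep <- data$arm %in% arms
  time <- data$time[keep]
  status <- as.integer(data$event_code[keep] == code)
  group <- as.integer(data$arm[keep] == arms[["experimental"]])
  if (sum(status) == 0) {
    abort(sprintf("No events of type '%s' in the data; the cause-specific hazard ratio is inestimable.", event))
  }
  fit <- cox_partial_newton(time, status, group)
  structure(
    c(fit, list(
      event = event, arms = arms, n = length(time), n_events = sum(status),
      n_events_experimental = sum(status[group == 1])
    )),
    class = "aerisk_cox"
  )
}

# Breslow partial log-likelihood pieces for a two-group comparison: for each
# distinct event time, the total events d, events in group 1 s1, and risk-set
# sizes n1 (group 1) and n0.
breslow_tables <- function(time, status, group) {
  et <- sort(unique(time[status == 1]))
  t1 <- sort(time[group == 1])
  t0 <- sort(time[group == 0])
  list(
    d = tabulate(match(time[status == 1], et), nbins = length(et)),
    s1 = tabulate(match(time[status == 1 & group == 1], et), nbins = length(et)),
    n1 = length(t1) - findInterval(et, t1, left.open = TRUE),
    n0 = length(t0) - findInterval(et, t0, left.open = TRUE)
  )
}

breslow_loglik <- function(beta, tb) {
  sum(tb$s1 * beta - tb$d * log(tb$n0 + tb$n1 * exp(beta)))
}

cox_partial_newton <- function(time, status, group, tol = 1e-8, max_iter = 50) {
  tb <- breslow_tables(time, status, group)
  s1_total <- sum(tb$s1)
  monotone <- s1_total == 0 || s1_total == sum(tb$d)
  if (monotone) {
    return(list(
      coef = if (s1_total == 0) -Inf else Inf, se = NA_real_,
      loglik = NA_real_, iter = 0L, converged = FALSE, monotone = TRUE,
      breslow = tb
    ))
  }
  beta <- 0
  ll <- breslow_loglik(beta, tb)
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    mu <- tb$n1 * exp(beta) / (tb$n0 + tb$n1 * exp(beta))
    score <- s1_total - sum(tb$d * mu)
    info <- sum(tb$d * mu * (1 - mu))
    if (info <= 0) {
      # no between-arm information at any event time: partial likelihood is
      # flat or one-sided, the estimate is not identified
      return(list(
        coef = NA_real_, se = NA_real_, loglik = ll, iter = iter,
        converged = FALSE, monotone = TRUE, breslow = tb
      ))
    }
    step <- score / info
    new_beta <- beta + step
    new_ll <- breslow_loglik(new_beta, tb)
    halvings <- 0
    while ((!is.finite(new_ll) || new_ll < ll) && halvings < 20) {
      step <- step / 2
      new_beta <- beta + step
      new_ll <- breslow_loglik(new_beta, tb)
      halvings <- halvings + 1
    }
    done <- abs(step) < tol
    beta <- new_beta
    ll <- new_ll
    if (done) {
      converged <- TRUE
      break
    }
  }
  mu <- tb$n1 * exp(beta) / (tb$n0 + tb$n1 * exp(beta))
  info <- sum(tb$d * mu * (1 - mu))
  list(
    coef = beta, se = sqrt(1 / info), loglik = ll, iter = iter,
    converged = converged, monotone = FALSE, breslow = tb
  )
}

#' @export
print.aerisk_cox <- function(x, ...) {
  cat(sprintf(
    "<aerisk_cox> cause-specific Cox fit, event '%s' (%d events / %d subjects)\n",
    x$event, x$n_events, x$n
  ))
  if (x$monotone) {
    cat("  monotone partial likelihood: all events in one arm, estimate diverges\n")
  } else {
    cat(sprintf(
      "  log HR = %.4f (SE %.4f), HR = %.4f; %d Newton-Raphson iterations\n",
      x$coef, x$se, exp(x$coef), x$iter
    ))
  }
  invisible(x)
}

#' @export
tidy.aerisk_cox <- function(x, conf.int = TRUE, conf.level = 0.95,
                            exponentiate = FALSE, ...) {
  est <- x$coef
  se <- x$se
  z <- qnorm(1 - (1 - conf.level) / 2)
  out <- tibble::tibble(
    term = paste0("arm", x$arms[["experimental"]]),
    estimate = if (exponentiate) exp(est) else est,
    std.error = se,
    statistic = est / se,
    p.value = 2 * pnorm(-abs(est / se))
  )
  if (conf.int) {
    out$conf.low <- est - z * se
    out$conf.high <- est + z * se
    if (exponentiate) {
      out$conf.low <- exp(out$conf.low)
      out$conf.high <- exp(out$conf.high)
    }
  }
  out
}

#' @export
glance.aerisk_cox <- function(x, ...) {
  tibble::tibble(
    n = x$n, nevent = x$n_events, logLik = x$loglik,
    iter = x$iter, converged = x$converged, monotone = x$monotone
  )
}

#' Cause-specific Cox hazard ratio
#'
#' The gold-standard relative-effect estimator on the hazard scale: the
#' hazard ratio from a two-group cause-specific Cox regression (see
#' [fit_cause_specific_cox()]), with a Wald interval from the observed
#' information. Hazard ratios use the full follow-up and carry no evaluation
#' time. A monotone partial likelihood (all events of the type in one arm)
#' yields `defined = FALSE` with the `diverged` flag set.
#'
#' @inheritParams fit_cause_specific_cox
#' @param level Confidence level.
#' @export
cox_hr <- function(data, event = c("ae", "ce"), level = 0.95,
                   experimental = NULL, control = NULL) {
  event <- rlang::arg_match(event)
  fit <- fit_cause_specific_cox(data, event, experimental, control)
  measure <- paste0("hr_", event)
  if (fit$monotone) {
    return(new_relative_effect(
      measure, "cox", NA_real_, NA_real_, NA_real_, NA_real_, level,
      NA_real_, FALSE, diverged = TRUE
    ))
  }
  z <- qnorm(1 - (1 - level) / 2)
  new_relative_effect(
    measure, "cox", NA_real_, exp(fit$coef),
    exp(fit$coef - z * fit$se), exp(fit$coef + z * fit$se),
    level, fit$se^2, TRUE
  )
}

#' Ratio of a comparator effect to its gold standard, with bootstrap CI
#'
#' Computes the relative effect with a comparator estimator and with the
#' corresponding gold standard on the same dataset, returns their ratio, and
#' attaches a percentile confidence interval from patient-level bootstrap
#' resampling stratified by arm. Bootstrapping is used because the two
#' effects are computed on the same subjects and are therefore dependent.
#' For `measure = "rr"` the gold standard is the risk ratio over arm-wise
#' Aalen-Johansen estimates; for `measure = "idr"` the comparator is the AE
#' incidence-density ratio and the gold standard the cause-specific Cox
#' hazard ratio.
#'
#' @inheritParams risk_ratio
#' @param measure `"rr"` or `"idr"`.
#' @param B Number of bootstrap resamples.
#' @param seed Integer seed; identical seeds give identical intervals.
#' @return A one-row tibble with the ratio, percentile CI, and the count of
#'   resamples dropped because an effect was undefined there.
#' @export
ratio_to_gold <- function(data, basis = "ip", measure = c("rr", "idr"),
                          tau = max_eval_time(data), B = 999, seed = NULL,
                          level = 0.95, experimental = NULL, control = NULL) {
  measure <- rlang::arg_match(measure)
  arms <- comparison_arms(data, experimental, control)
  pair <- function(d) {
    if (measure == "rr") {
      comp <- risk_ratio(d, basis, tau,
        experimental = arms[["experimental"]], control = arms[["control"]]
      )
      gold <- risk_ratio(d, "aje", tau,
        experimental = arms[["experimental"]], control = arms[["control"]]
      )
    } else {
      comp <- incidence_density_ratio(d, "ae", tau,
        experimental = arms[["experimental"]], control = arms[["control"]]
      )
      gold <- tryCatch(
        cox_hr(d, "ae",
          experimental = arms[["experimental"]], control = arms[["control"]]
        ),
        error = function(e) new_relative_effect(
          "hr_ae", "cox", NA_real_, NA_real_, NA_real_, NA_real_, 0.95,
          NA_real_, FALSE
        )
      )
    }
    if (!comp$defined || !gold$defined) {
      return(NA_real_)
    }
    comp$estimate / gold$estimate
  }
  point <- pair(data)
  if (is.na(point)) {
    abort("Comparator or gold-standard effect is undefined on the full data.")
  }
  by_arm <- split(seq_len(nrow(data)), data$arm)
  boot_once <- function() {
    idx <- unlist(lapply(by_arm, function(i) sample(i, length(i), replace = TRUE)))
    d <- data[idx, , drop = FALSE]
    d$subject_id <- paste0("b", seq_len(nrow(d)))
    pair(d)
  }
  draws <- withr::with_seed(
    seed %||% sample.int(.Machine$integer.max, 1),
    vapply(seq_len(B), function(i) boot_once(), numeric(1))
  )
  ok <- draws[!is.na(draws)]
  alpha <- 1 - level
  ci <- if (length(ok) > 0) {
    quantile(ok, c(alpha / 2, 1 - alpha / 2), names = FALSE, type = 7)
  } else {
    c(NA_real_, NA_real_)
  }
  tibble::tibble(
    measure = measure,
    basis = if (measure == "rr") basis else "id",
    tau = tau, estimate = point, lower = ci[1], upper = ci[2],
    level = level, B = B, n_dropped = sum(is.na(draws))
  )
}
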