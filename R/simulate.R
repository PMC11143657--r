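# Constant-hazards competing-risks trial generator with closed-form truths.
#
# The data-generating model per subject: a latent first-event time that is
# exponential with rate alpha + beta (AE hazard alpha, competing-event hazard
# beta), the event type AE with probability alpha / (alpha + beta); censoring
# as the minimum of an exponential(gamma) random-censoring time and an
# administrative horizon reduced by a uniform staggered-entry offset (the
# mechanism behind varying follow-up times). Time unit: years, hazards per
# year, by convention.

#' Scenario configuration for the constant-hazards simulator
#'
#' @param n_per_arm Subjects per arm.
#' @param alpha_e,alpha_c AE hazards (per time unit) in the experimental and
#'   control arm. Leave `alpha_c = NULL` for a one-arm scenario.
#' @param beta_e,beta_c Competing-event hazards. `beta_c` defaults to
#'   `beta_e`.
#' @param gamma Random-censoring hazard (0 = none).
#' @param admin_time Administrative censoring horizon (end of study);
#'   `NULL` for none.
#' @param entry_window Width of the uniform staggered-entry window. Entry
#'   offsets in \[0, `entry_window`\] truncate the administrative follow-up;
#'   0 recovers common follow-up.
#' @param seed Integer seed stored with the scenario; [simulate_trial()]
#'   uses it by default.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_per_arm, alpha_e, alpha_c = NULL,
                            beta_e = 0, beta_c = NULL, gamma = 0,
                            admin_time = NULL, entry_window = 0, seed = NULL) {
  if (n_per_arm < 1) abort("`n_per_arm` must be a positive integer.")
  two_arm <- !is.null(alpha_c)
  if (is.null(beta_c)) beta_c <- beta_e
  haz <- c(alpha_e, beta_e, gamma, entry_window, if (two_arm) c(alpha_c, beta_c))
  if (any(haz < 0) || any(!is.finite(haz))) {
    abort("Hazards, `gamma` and `entry_window` must be finite and nonnegative.")
  }
  if (alpha_e + beta_e + (if (two_arm) alpha_c + beta_c else 0) == 0) {
    abort("At least one event hazard must be positive.")
  }
  if (!is.null(admin_time)) {
    if (admin_time <= 0) abort("`admin_time` must be positive when set.")
    if (entry_window >= admin_time) {
      abort("`entry_window` must be smaller than `admin_time`.")
    }
  }
  for (arm in if (two_arm) c("e", "c") else "e") {
    a <- if (arm == "e") alpha_e else alpha_c
    b <- if (arm == "e") beta_e else beta_c
    if (a + b == 0 && gamma == 0 && is.null(admin_time)) {
      abort("An arm with no event hazard needs censoring to yield finite times.")
    }
  }
  structure(
    list(
      n_per_arm = as.integer(n_per_arm), alpha_e = alpha_e, alpha_c = alpha_c,
      beta_e = beta_e, beta_c = beta_c, gamma = gamma,
      admin_time = admin_time, entry_window = entry_window, seed = seed,
      two_arm = two_arm
    ),
    class = "scenario_config"
  )
}

#' Simulate a competing-risks trial under constant hazards
#'
#' First-event times are drawn as a total-rate exponential with a binomial
#' type split (equivalent to latent competing exponentials, but cheaper and
#' exact). Identical configurations and seeds give identical datasets.
#'
#' @param config A [scenario_config()].
#' @param seed Overrides the seed stored in the config.
#' @return A [trial_data] tibble with arms `"experimental"` (and
#'   `"control"` for two-arm scenarios).
#' @export
simulate_trial <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "scenario_config"))
  draw_arm <- function(arm_label, prefix, alpha, beta) {
    n <- config$n_per_arm
    rate <- alpha + beta
    t_event <- if (rate > 0) rexp(n, rate) else rep(Inf, n)
    is_ae <- if (rate > 0) rbinom(n, 1, alpha / rate) == 1 else rep(FALSE, n)
    entry <- if (config$entry_window > 0) runif(n, 0, config$entry_window) else rep(0, n)
    c_rand <- if (config$gamma > 0) rexp(n, config$gamma) else rep(Inf, n)
    c_admin <- if (!is.null(config$admin_time)) config$admin_time - entry else rep(Inf, n)
    cens <- pmin(c_rand, c_admin)
    time <- pmin(t_event, cens)
    code <- ifelse(t_event <= cens, ifelse(is_ae, EVENT_AE, EVENT_CE), EVENT_CENSORED)
    tibble::tibble(
      subject_id = sprintf("%s%05d", prefix, seq_len(n)),
      arm = arm_label, time = time, event_code = as.integer(code)
    )
  }
  gen <- function() {
    rec <- draw_arm("experimental", "E", config$alpha_e, config$beta_e)
    if (config$two_arm) {
      rec <- dplyr::bind_rows(
        rec, draw_arm("control", "C", config$alpha_c, config$beta_c)
      )
    }
    rec
  }
  records <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  trial_data(records, trial_id = "simulated", ae_id = "simulated_ae")
}

check_nonneg <- function(...) {
  vals <- c(...)
  if (any(vals < 0) || any(is.na(vals))) {
    abort("Hazards and times must be nonnegative.")
  }
}

#' Closed-form cumulative incidences under constant hazards
#'
#' With constant AE hazard `alpha` and competing-event hazard `beta`, the
#' true AE cumulative incidence is
#' \deqn{F_{AE}(t) = \frac{\alpha}{\alpha+\beta}\bigl(1 -
#' e^{-(\alpha+\beta)t}\bigr),} and symmetrically for the competing event.
#' `km_estimand()` returns \eqn{1 - e^{-\alpha t}}, the quantity one minus
#' Kaplan-Meier (censoring competing events) actually targets; it is always
#' at least `true_cif_ae()`, with equality iff `beta = 0` or `t = 0`.
#'
#' @param alpha,beta Nonnegative hazards.
#' @param t Nonnegative time(s).
#' @return Probability vector.
#' @export
true_cif_ae <- function(alpha, beta, t) {
  check_nonneg(alpha, beta, t)
  s <- alpha + beta
  if (alpha == 0 || s == 0) {
    return(rep(0, length(t)))
  }
  alpha / s * (1 - exp(-s * t))
}

#' @rdname true_cif_ae
#' @export
true_cif_ce <- function(alpha, beta, t) {
  true_cif_ae(beta, alpha, t)
}

#' @rdname true_cif_ae
#' @export
km_estimand <- function(alpha, t) {
  check_nonneg(alpha, t)
  1 - exp(-alpha * t)
}

#' Closed-form truths of a scenario
#'
#' The analytic companion of [simulate_trial()]: true cumulative incidences,
#' the one-minus-Kaplan-Meier estimand, the true risk ratio at each time, and
#' the true hazard ratio \eqn{\alpha_E/\alpha_C}.
#'
#' @param config A [scenario_config()].
#' @param t Time(s) at which to evaluate.
#' @return A tibble with one row per time point.
#' @export
scenario_truth <- function(config, t) {
  stopifnot(inherits(config, "scenario_config"))
  out <- tibble::tibble(
    t = t,
    cif_ae_experimental = true_cif_ae(config$alpha_e, config$beta_e, t),
    cif_ce_experimental = true_cif_ce(config$alpha_e, config$beta_e, t),
    km_estimand_experimental = km_estimand(config$alpha_e, t)
  )
  if (config$two_arm) {
    out <- dplyr::mutate(out,
      cif_ae_control = true_cif_ae(config$alpha_c, config$beta_c, t),
      cif_ce_control = true_cif_ce(config$alpha_c, config$beta_c, t),
      km_estimand_control = km_estimand(config$alpha_c, t),
      true_rr = .data$cif_ae_experimental / .data$cif_ae_control,
      true_hr = config$alpha_e / config$alpha_c
    )
  }
  out
}
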