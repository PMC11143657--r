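# Risk ratios, incidence-density ratios, cause-specific Cox fits, and the
# bootstrap comparison to gold standards.

two_arm_fixture <- function(seed = 3, n = 60) {
  simulate_trial(scenario_config(
    n_per_arm = n, alpha_e = 0.3, alpha_c = 0.15, beta_e = 0.2, beta_c = 0.2,
    gamma = 0.1, seed = seed
  ))
}

mirror_arms <- function(records) {
  mirrored <- tibble::as_tibble(records)
  mirrored$arm <- ifelse(mirrored$arm == "experimental", "control", "experimental")
  trial_data(mirrored)
}

test_that("identical arms give a relative effect of exactly one, for every measure", {
  one_arm <- tibble::as_tibble(toy4())
  both <- trial_data(dplyr::bind_rows(
    one_arm,
    dplyr::mutate(one_arm, arm = "control", subject_id = paste0(subject_id, "c"))
  ))
  for (basis in c("aje", "ip", "id", "id_ce", "one_minus_km")) {
    expect_equal(risk_ratio(both, basis, tau = 4)$estimate, 1)
  }
  expect_equal(incidence_density_ratio(both, "ae", tau = 4)$estimate, 1)
  expect_equal(cox_hr(both, "ae")$estimate, 1, tolerance = 1e-8)
})

test_that("the delta rule drives the log-scale variance and CI width of the risk ratio", {
  d <- two_arm_fixture()
  tau <- max_eval_time(d)
  rr <- risk_ratio(d, "aje", tau = tau)
  qe <- aalen_johansen(d, arm = "experimental", tau = tau)
  qc <- aalen_johansen(d, arm = "control", tau = tau)
  expect_equal(rr$estimate, qe$estimate / qc$estimate)
  expect_equal(
    rr$log_variance,
    qe$variance / qe$estimate^2 + qc$variance / qc$estimate^2
  )
  # log-CI width is 2 z sqrt(var) by construction
  expect_equal(
    log(rr$upper) - log(rr$lower),
    2 * qnorm(0.975) * sqrt(rr$log_variance)
  )
  # worked delta-rule example: q_E = 0.2 (var 0.0016), q_C = 0.1 (var 0.0009)
  expect_equal(0.0016 / 0.2^2 + 0.0009 / 0.1^2, 0.13)
})

test_that("a zero-probability arm yields defined = FALSE, not an error", {
  d <- trial_data(data.frame(
    subject_id = paste0("s", 1:6),
    arm = rep(c("experimental", "control"), each = 3),
    time = c(1, 2, 3, 1, 2, 3),
    event_code = c(1, 1, 0, 0, 0, 2) # control arm has no AEs
  ))
  rr <- risk_ratio(d, "ip", tau = 3)
  expect_false(rr$defined)
  expect_true(is.na(rr$lower) && is.na(rr$upper))
  idr <- incidence_density_ratio(d, "ae", tau = 3)
  expect_false(idr$defined)
})

test_that("swapping arm labels inverts every relative effect exactly", {
  d <- two_arm_fixture(seed = 8)
  m <- mirror_arms(d)
  tau <- max_eval_time(d)
  expect_equal(risk_ratio(m, "aje", tau = tau)$estimate,
    1 / risk_ratio(d, "aje", tau = tau)$estimate,
    tolerance = 1e-12
  )
  expect_equal(incidence_density_ratio(m, "ae", tau = tau)$estimate,
    1 / incidence_density_ratio(d, "ae", tau = tau)$estimate,
    tolerance = 1e-12
  )
  expect_equal(cox_hr(m, "ae")$estimate, 1 / cox_hr(d, "ae")$estimate,
    tolerance = 1e-7
  )
})

test_that("incidence-density ratio: hand-worked Poisson example", {
  # experimental: 2 AEs in 10 person-units; control: 1 AE in 10
  d <- trial_data(data.frame(
    subject_id = paste0("s", 1:8),
    arm = rep(c("experimental", "control"), each = 4),
    time = c(1, 2, 3, 4, 2, 1, 3, 4),
    event_code = c(1, 1, 0, 0, 1, 0, 0, 0)
  ))
  idr <- incidence_density_ratio(d, "ae", tau = 4)
  expect_equal(idr$estimate, 2)
  expect_equal(idr$log_variance, 1 / 2 + 1 / 1)
})

test_that("Newton-Raphson matches the grid-search oracle for the Breslow partial likelihood", {
  fixtures <- list(
    cox_fixture6(),
    random_trial(5, seed = 31, arms = c("experimental", "control")),
    random_trial(4, seed = 77, arms = c("experimental", "control"),
                 p_codes = c(0.2, 0.6, 0.2))
  )
  for (d in fixtures) {
    status <- as.integer(d$event_code == 1)
    group <- as.integer(d$arm == "experimental")
    if (sum(status[group == 1]) == 0 || sum(status[group == 0]) == 0) next
    fit <- fit_cause_specific_cox(d, "ae")
    oracle <- grid_cox_oracle(d$time, status, group)
    if (!fit$converged || abs(oracle$beta) > 2.9) next # no interior optimum
    expect_lt(abs(fit$coef - oracle$beta), 1e-4)
    # the fitted likelihood is at least every grid value (up to grid precision)
    expect_gte(fit$loglik, oracle$loglik - 1e-6)
  }
})

test_that("the Cox fit agrees with survival::coxph under Breslow ties", {
  skip_if_not_installed("survival")
  for (seed in c(2, 9)) {
    d <- two_arm_fixture(seed = seed, n = 120)
    for (ev in c("ae", "ce")) {
      fit <- fit_cause_specific_cox(d, ev)
      code <- if (ev == "ae") 1 else 2
      ref <- survival::coxph(
        survival::Surv(time, event_code == code) ~ I(arm == "experimental"),
        data = d, ties = "breslow"
      )
      expect_equal(fit$coef, unname(coef(ref)), tolerance = 1e-6)
      expect_equal(fit$se, unname(sqrt(vcov(ref)[1, 1])), tolerance = 1e-6)
    }
  }
})

test_that("tidy and glance expose the Cox fit in broom shape", {
  fit <- fit_cause_specific_cox(two_arm_fixture(), "ae")
  td <- tidy(fit, exponentiate = TRUE)
  expect_named(td, c(
    "term", "estimate", "std.error", "statistic", "p.value",
    "conf.low", "conf.high"
  ))
  expect_equal(td$estimate, exp(fit$coef))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_lte(gl$iter, 50)
})

test_that("a monotone partial likelihood is flagged as diverging, not iterated", {
  d <- trial_data(data.frame(
    subject_id = paste0("s", 1:8),
    arm = rep(c("experimental", "control"), each = 4),
    time = 1:8,
    event_code = c(1, 1, 1, 0, 0, 0, 0, 0) # all AEs in the experimental arm
  ))
  hr <- cox_hr(d, "ae")
  expect_false(hr$defined)
  expect_true(hr$diverged)
  expect_error(cox_hr(dplyr::mutate(d, event_code = 0L), "ae"), "inestimable")
})

test_that("ratio to gold: self-comparison is degenerate at one, equality cases hold, seeds reproduce", {
  d <- two_arm_fixture(seed = 12, n = 50)
  tau <- max_eval_time(d)

  self <- ratio_to_gold(d, basis = "aje", measure = "rr", tau = tau, B = 50, seed = 1)
  expect_equal(self$estimate, 1)
  expect_equal(c(self$lower, self$upper), c(1, 1))

  # without censoring and at the maximal time, IP and AJE coincide, so the
  # ratio of their RRs is exactly one
  unc <- simulate_trial(scenario_config(
    n_per_arm = 40, alpha_e = 0.3, alpha_c = 0.2, beta_e = 0.3, seed = 5
  ))
  r <- ratio_to_gold(unc, basis = "ip", measure = "rr",
                     tau = max_eval_time(unc), B = 30, seed = 2)
  expect_equal(r$estimate, 1, tolerance = 1e-12)

  a <- ratio_to_gold(d, basis = "one_minus_km", measure = "rr", tau = tau, B = 60, seed = 7)
  b <- ratio_to_gold(d, basis = "one_minus_km", measure = "rr", tau = tau, B = 60, seed = 7)
  expect_equal(a, b)
  c_ <- ratio_to_gold(d, basis = "one_minus_km", measure = "rr", tau = tau, B = 60, seed = 8)
  expect_false(isTRUE(all.equal(a$lower, c_$lower)))

  idr <- ratio_to_gold(d, measure = "idr", tau = tau, B = 40, seed = 3)
  expect_true(idr$estimate > 0)
  expect_true(idr$lower <= idr$estimate && idr$estimate <= idr$upper)
})

test_that("an undefined effect on the full data is an error for ratio_to_gold", {
  d <- trial_data(data.frame(
    subject_id = paste0("s", 1:6),
    arm = rep(c("experimental", "control"), each = 3),
    time = c(1, 2, 3, 1, 2, 3),
    event_code = c(1, 1, 0, 0, 0, 0)
  ))
  expect_error(ratio_to_gold(d, basis = "ip", measure = "rr", tau = 3, B = 10, seed = 1),
    "undefined"
  )
})
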