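# Unit and property tests for the five absolute-risk estimators.

test_that("counts, person-time and variances follow their defining formulas", {
  toy <- toy4()
  ip <- incidence_proportion(toy, tau = 4)
  expect_equal(ip$variance, 0.5 * 0.5 / 4)
  expect_equal(ip[c("n", "d_ae", "d_ce", "n_cens")], tibble::tibble(
    n = 4L, d_ae = 2L, d_ce = 1L, n_cens = 1L
  ), ignore_attr = TRUE)

  id <- incidence_density(toy, tau = 4, event = "ae")
  expect_equal(id$person_time, 10)
  expect_equal(id$rate_variance, 2 / 100)

  # restricting tau truncates both counts and person-time
  ip2 <- incidence_proportion(toy, tau = 2.5)
  expect_equal(ip2$estimate, 1 / 4)
  expect_equal(ip2$person_time, 1 + 2 + 2.5 + 2.5)

  # transform variance: delta method around the Poisson rate
  pt <- prob_transform_id(toy, tau = 4)
  lambda <- 0.2
  expect_equal(pt$variance, (4 * exp(-lambda * 4))^2 * 2 / 100)
})

test_that("all-censored and no-event edge cases behave", {
  cens <- trial_data(data.frame(
    subject_id = paste0("s", 1:3), arm = "experimental",
    time = c(1, 2, 3), event_code = 0
  ))
  for (fn in list(incidence_proportion, prob_transform_id, prob_transform_id_ce,
                  one_minus_km, aalen_johansen)) {
    expect_equal(fn(cens, tau = 3)$estimate, 0)
  }
  expect_equal(incidence_density(cens, tau = 3, event = "ae")$rate, 0)
  expect_error(incidence_proportion(toy4(), arm = "control"), class = "aerisk_validation_error")
})

test_that("evaluation beyond the last observation carries forward and is flagged", {
  toy <- toy4()
  aj <- aalen_johansen(toy, tau = 10)
  expect_true(aj$tau_beyond_data)
  expect_equal(aj$estimate, aalen_johansen(toy, tau = 4)$estimate)
  expect_false(aalen_johansen(toy, tau = 4)$tau_beyond_data)
  # step lookup: zero before the first jump, constant between jumps
  curve <- risk_curve(aalen_johansen(toy, tau = 4))
  expect_equal(curve_value(curve, c(0.5, 1, 1.5, 3.9, 4, 100)),
               c(0, 0.25, 0.25, 0.25, 0.75, 0.75))
})

test_that("conservation holds at every jump time (machine precision)", {
  for (seed in 1:20) {
    d <- random_trial(n = sample(3:30, 1), seed = seed)
    ae <- risk_curve(aalen_johansen(d, tau = max_eval_time(d), event = "ae"))
    ce <- risk_curve(aalen_johansen(d, tau = max_eval_time(d), event = "ce"))
    expect_equal(ae$time, ce$time)
    expect_equal(ae$estimate + ce$estimate + ae$surv_all,
      rep(1, nrow(ae)),
      tolerance = 1e-12
    )
  }
})

test_that("with no competing events the Aalen-Johansen equals one minus Kaplan-Meier", {
  for (seed in 1:10) {
    d <- random_trial(n = 20, seed = seed, p_codes = c(0.4, 0.6, 0)) # no CEs
    tau <- max_eval_time(d)
    aj <- aalen_johansen(d, tau = tau)
    km <- one_minus_km(d, tau = tau)
    expect_equal(aj$estimate, km$estimate, tolerance = 1e-12)
    grid <- seq(0, tau, length.out = 30)
    expect_equal(curve_value(risk_curve(aj), grid), curve_value(risk_curve(km), grid),
      tolerance = 1e-12
    )
  }
})

test_that("without censoring the incidence proportion equals the Aalen-Johansen at the maximal time", {
  for (seed in 1:10) {
    d <- random_trial(n = 15, seed = seed, p_codes = c(0, 0.5, 0.5)) # no censoring
    tau <- max_eval_time(d)
    expect_equal(incidence_proportion(d, tau = tau)$estimate,
      aalen_johansen(d, tau = tau)$estimate,
      tolerance = 1e-12
    )
  }
})

test_that("the CE-aware transform collapses to the plain transform without CEs", {
  d <- random_trial(n = 20, seed = 5, p_codes = c(0.4, 0.6, 0))
  expect_equal(prob_transform_id_ce(d, tau = 3)$estimate,
    prob_transform_id(d, tau = 3)$estimate,
    tolerance = 1e-14
  )
  expect_equal(prob_transform_id_ce(d, tau = 3)$variance,
    prob_transform_id(d, tau = 3)$variance,
    tolerance = 1e-14
  )
})

test_that("step curves match the recursive oracle and survival::survfit on small data", {
  skip_if_not_installed("survival")
  for (seed in 1:25) {
    d <- random_trial(n = sample(3:8, 1), seed = 100 + seed)
    tau <- max_eval_time(d)
    grid <- sort(unique(c(d$time, d$time / 2, tau)))
    aj <- risk_curve(aalen_johansen(d, tau = tau))
    km <- risk_curve(one_minus_km(d, tau = tau))
    for (t in grid) {
      expect_equal(curve_value(aj, t), oracle_cif(d$time, d$event_code, 1, t),
        tolerance = 1e-12
      )
      expect_equal(curve_value(km, t), oracle_one_minus_km(d$time, d$event_code, t),
        tolerance = 1e-12
      )
    }
    ev <- factor(d$event_code, levels = 0:2, labels = c("cens", "ae", "ce"))
    sf <- survival::survfit(survival::Surv(d$time, ev) ~ 1)
    expect_equal(
      curve_value(aj, sf$time),
      unname(sf$pstate[, match("ae", sf$states)]),
      tolerance = 1e-10
    )
  }
})

test_that("pointwise variances agree with survival's and with the bootstrap", {
  skip_if_not_installed("survival")
  d <- simulate_trial(scenario_config(
    n_per_arm = 300, alpha_e = 0.2, beta_e = 0.2, gamma = 0.15, seed = 9
  ))
  tau <- 5
  aj <- aalen_johansen(d, tau = tau)
  km <- one_minus_km(d, tau = tau)

  ev <- factor(d$event_code, levels = 0:2, labels = c("cens", "ae", "ce"))
  sf <- survival::survfit(survival::Surv(d$time, ev) ~ 1)
  i <- max(which(sf$time <= tau))
  j <- match("ae", sf$states)
  expect_equal(aj$estimate, unname(sf$pstate[i, j]), tolerance = 1e-10)
  expect_equal(sqrt(aj$variance), unname(sf$std.err[i, j]), tolerance = 0.1)

  sk <- survival::survfit(survival::Surv(d$time, d$event_code == 1) ~ 1)
  k <- max(which(sk$time <= tau))
  expect_equal(km$estimate, 1 - sk$surv[k], tolerance = 1e-10)
  expect_equal(sqrt(km$variance), sk$std.err[k] * sk$surv[k], tolerance = 1e-6)

  boot <- withr::with_seed(21, vapply(1:400, function(b) {
    idx <- sample(nrow(d), replace = TRUE)
    dd <- d[idx, ]
    dd$subject_id <- as.character(seq_len(nrow(dd)))
    aalen_johansen(trial_data(dd), tau = tau)$estimate
  }, numeric(1)))
  expect_equal(sqrt(aj$variance), sd(boot), tolerance = 0.15)
})

test_that("ordering: one minus Kaplan-Meier dominates the Aalen-Johansen, which dominates the incidence proportion at the maximal time", {
  for (seed in 1:30) {
    d <- random_trial(n = sample(5:40, 1), seed = 200 + seed)
    tau <- max_eval_time(d)
    grid <- seq(0, tau, length.out = 25)
    km <- curve_value(risk_curve(one_minus_km(d, tau = tau)), grid)
    aj <- curve_value(risk_curve(aalen_johansen(d, tau = tau)), grid)
    expect_true(all(km - aj >= -1e-12))
    expect_gte(
      aalen_johansen(d, tau = tau)$estimate,
      incidence_proportion(d, tau = tau)$estimate - 1e-12
    )
  }
})

test_that("under constant hazards the consistent estimators converge to the closed-form truth", {
  mae <- function(n, seed) {
    cfg <- scenario_config(
      n_per_arm = n, alpha_e = 0.15, beta_e = 0.25, gamma = 0.1, seed = seed
    )
    d <- simulate_trial(cfg)
    grid <- c(2, 4, 6, 8)
    truth <- true_cif_ae(0.15, 0.25, grid)
    aj <- vapply(grid, function(t) aalen_johansen(d, tau = t)$estimate, numeric(1))
    idce <- vapply(grid, function(t) prob_transform_id_ce(d, tau = t)$estimate, numeric(1))
    c(aje = mean(abs(aj - truth)), id_ce = mean(abs(idce - truth)))
  }
  small <- rowMeans(vapply(1:5, function(s) mae(200, s), numeric(2)))
  big <- rowMeans(vapply(1:5, function(s) mae(2000, 100 + s), numeric(2)))
  expect_lt(big[["aje"]], small[["aje"]])
  expect_lt(big[["aje"]], 0.01)
  expect_lt(big[["id_ce"]], 0.02)
})

test_that("estimate_ae_risk stacks arms and estimators with cloglog confidence limits inside [0, 1]", {
  d <- simulate_trial(scenario_config(
    n_per_arm = 80, alpha_e = 0.3, alpha_c = 0.15, beta_e = 0.2, gamma = 0.1,
    seed = 4
  ))
  out <- estimate_ae_risk(d, ci_level = 0.95)
  expect_equal(nrow(out), 10)
  expect_setequal(unique(out$arm), c("experimental", "control"))
  ok <- out$estimate > 0 & out$estimate < 1
  expect_true(all(out$lower[ok] <= out$estimate[ok] & out$estimate[ok] <= out$upper[ok]))
  expect_true(all(out$lower >= 0 & out$upper <= 1))
})
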