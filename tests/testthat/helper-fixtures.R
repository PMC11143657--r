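# Fixtures and independent oracles used across the suite.

# The four-subject worked example: AE at 1, competing event at 2, censored at
# 3, AE at 4.
toy4 <- function(arm = "experimental") {
  trial_data(
    data.frame(
      subject_id = paste0("s", 1:4), arm = arm,
      time = 1:4, event_code = c(1, 2, 0, 1)
    ),
    trial_id = "toy", ae_id = "toy_ae"
  )
}

# Small random dataset generator for property tests. Times are rounded to
# one decimal so ties (including event/censoring ties) occur regularly.
random_trial <- function(n, seed, arms = "experimental", p_codes = c(0.3, 0.4, 0.3)) {
  withr::with_seed(seed, {
    trial_data(data.frame(
      subject_id = paste0("s", seq_len(n * length(arms))),
      arm = rep(arms, each = n),
      time = pmax(round(rexp(n * length(arms), 0.5), 1), 0.1),
      event_code = sample(0:2, n * length(arms), replace = TRUE, prob = p_codes)
    ))
  })
}

# Independent oracle: cumulative incidence of one event type by hand-coded
# recursion over the risk set. Processes the earliest remaining time point,
# adds its contribution S(t-) * d_event/n, rescales survival, and recurses on
# the strictly later records.
oracle_cif <- function(time, code, target, at) {
  recurse <- function(time, code, surv) {
    if (length(time) == 0) {
      return(0)
    }
    t1 <- min(time)
    if (t1 > at) {
      return(0)
    }
    n <- length(time)
    d_target <- sum(time == t1 & code == target)
    d_all <- sum(time == t1 & code != 0)
    keep <- time > t1
    surv * d_target / n + recurse(time[keep], code[keep], surv * (1 - d_all / n))
  }
  recurse(time, code, 1)
}

# Same recursion for the AE-only product limit (competing events censored).
oracle_one_minus_km <- function(time, code, at) {
  recurse <- function(time, code, surv) {
    if (length(time) == 0 || min(time) > at) {
      return(1 - surv)
    }
    t1 <- min(time)
    n <- length(time)
    d <- sum(time == t1 & code == 1)
    keep <- time > t1
    recurse(time[keep], code[keep], surv * (1 - d / n))
  }
  recurse(time, code, 1)
}

# Grid-search oracle for the two-group Breslow partial likelihood.
grid_cox_oracle <- function(time, status, group, grid = seq(-3, 3, by = 1e-4)) {
  et <- sort(unique(time[status == 1]))
  d <- vapply(et, function(t) sum(status == 1 & time == t), numeric(1))
  s1 <- vapply(et, function(t) sum(status == 1 & time == t & group == 1), numeric(1))
  n1 <- vapply(et, function(t) sum(time >= t & group == 1), numeric(1))
  n0 <- vapply(et, function(t) sum(time >= t & group == 0), numeric(1))
  ll <- vapply(grid, function(b) {
    sum(s1 * b - d * log(n0 + n1 * exp(b)))
  }, numeric(1))
  list(beta = grid[which.max(ll)], loglik = max(ll), grid = grid, ll = ll)
}

# A small two-arm fixture with events of both types in both arms.
cox_fixture6 <- function() {
  trial_data(data.frame(
    subject_id = paste0("s", 1:6),
    arm = rep(c("experimental", "control"), each = 3),
    time = c(1, 3, 5, 2, 4, 6),
    event_code = c(1, 1, 0, 1, 2, 1)
  ))
}
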