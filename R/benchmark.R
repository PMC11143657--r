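# Bias quantification: every estimator against the Aalen-Johansen benchmark
# on datasets, and against analytic truth on simulated scenarios.

#' Ratio of each estimator to the Aalen-Johansen benchmark
#'
#' For each dataset, arm, and estimator, computes the AE-probability estimate
#' and the Aalen-Johansen estimate at the dataset's (pooled) maximal
#' evaluation time — or a fixed `tau` — and their ratio. Deviation of the
#' ratio from 1 is the empirical bias relative to the gold standard. Units
#' where the benchmark is 0 are excluded and counted.
#'
#' @param datasets A list of [trial_data] tibbles (a single dataset is
#'   accepted too).
#' @param estimators Comparator estimators (any of `"ip"`, `"id"`,
#'   `"id_ce"`, `"one_minus_km"`, `"aje"`).
#' @param tau Fixed evaluation time; default uses each dataset's maximal
#'   evaluation time (sensitivity runs at shorter times pass a value).
#' @return A `bias_report` tibble (one row per dataset, arm, estimator) with
#'   an `n_excluded` attribute; pool across units with [pool_bias()].
#' @export
bias_vs_gold <- function(datasets,
                         estimators = c("ip", "id", "id_ce", "one_minus_km"),
                         tau = NULL) {
  if (inherits(datasets, "trial_data")) datasets <- list(datasets)
  estimators <- match.arg(estimators, RISK_ESTIMATORS, several.ok = TRUE)
  excluded <- 0L
  rows <- purrr::map_dfr(datasets, function(d) {
    tau_d <- tau %||% max_eval_time(d)
    purrr::map_dfr(sort(unique(d$arm)), function(a) {
      gold <- aalen_johansen(d, arm = a, tau = tau_d)$estimate
      if (gold <= 0) {
        excluded <<- excluded + 1L
        return(tibble::tibble())
      }
      ests <- estimate_ae_risk(d[d$arm == a, ], tau = tau_d, estimators = estimators)
      tibble::tibble(
        trial_id = trial_id(d), ae_id = ae_id(d), arm = a,
        estimator = ests$estimator, tau = tau_d,
        estimate = ests$estimate, gold = gold,
        ratio = ests$estimate / gold
      )
    })
  })
  structure(rows,
    class = c("bias_report", class(rows)),
    n_excluded = excluded, reference = "aje"
  )
}

#' Run simulated scenarios and measure bias against analytic truth
#'
#' For each scenario and replicate, simulates a trial, evaluates all
#' requested absolute-risk estimators at the replicate's maximal evaluation
#' time, and divides by the closed-form true AE probability at that time.
#' Fully seeded: identical calls give identical reports. Per-replicate
#' estimation failures are counted, not fatal.
#'
#' @param configs A list of [scenario_config()]s (or a single one).
#' @param reps Replicates per scenario.
#' @param seed Integer master seed.
#' @param estimators As in [bias_vs_gold()].
#' @return A `bias_report` tibble, one row per scenario, replicate, arm, and
#'   estimator, with columns `estimate`, `truth` and `ratio`; pool with
#'   [pool_bias()].
#' @export
run_scenarios <- function(configs, reps, seed = 1,
                          estimators = RISK_ESTIMATORS) {
  if (inherits(configs, "scenario_config")) configs <- list(configs)
  estimators <- match.arg(estimators, RISK_ESTIMATORS, several.ok = TRUE)
  if (reps < 1) abort("`reps` must be at least 1.")
  rep_seeds <- withr::with_seed(
    seed, matrix(sample.int(2^31 - 1, length(configs) * reps),
      nrow = length(configs)
    )
  )
  failures <- 0L
  rows <- purrr::map_dfr(seq_along(configs), function(i) {
    cfg <- configs[[i]]
    purrr::map_dfr(seq_len(reps), function(j) {
      res <- tryCatch({
        d <- simulate_trial(cfg, seed = rep_seeds[i, j])
        tau <- max_eval_time(d)
        purrr::map_dfr(sort(unique(d$arm)), function(a) {
          alpha <- if (a == "control") cfg$alpha_c else cfg$alpha_e
          beta <- if (a == "control") cfg$beta_c else cfg$beta_e
          truth <- true_cif_ae(alpha, beta, tau)
          ests <- estimate_ae_risk(d[d$arm == a, ], tau = tau, estimators = estimators)
          tibble::tibble(
            scenario = i, rep = j, arm = a, estimator = ests$estimator,
            tau = tau, estimate = ests$estimate, truth = truth,
            ratio = ests$estimate / truth
          )
        })
      }, error = function(e) NULL)
      if (is.null(res)) {
        failures <<- failures + 1L
        return(tibble::tibble())
      }
      res
    })
  })
  structure(rows,
    class = c("bias_report", class(rows)),
    n_failures = failures, reference = "truth", seed = seed
  )
}

#' Pool a bias report across units
#'
#' Summarizes the ratio-to-benchmark per estimator (and per scenario when
#' present). Ratios are pooled on the log scale and exponentiated at report
#' time; the default center is the median with an interquartile range, with
#' the (geometric) mean and Monte-Carlo standard error available as an
#' option.
#'
#' @param report A `bias_report` from [bias_vs_gold()] or [run_scenarios()].
#' @param center `"median"` (with IQR) or `"mean"` (geometric, with MC
#'   standard error of the log ratio).
#' @return A tibble with one row per (scenario ×) estimator.
#' @export
pool_bias <- function(report, center = c("median", "mean")) {
  center <- rlang::arg_match(center)
  keys <- intersect(c("scenario", "estimator"), names(report))
  grouped <- dplyr::group_by(report, dplyr::across(dplyr::all_of(keys)))
  out <- if (center == "median") {
    dplyr::summarise(grouped,
      n_units = dplyr::n(),
      ratio = exp(median(log(.data$ratio))),
      ratio_q25 = exp(quantile(log(.data$ratio), 0.25, names = FALSE)),
      ratio_q75 = exp(quantile(log(.data$ratio), 0.75, names = FALSE)),
      .groups = "drop"
    )
  } else {
    dplyr::summarise(grouped,
      n_units = dplyr::n(),
      ratio = exp(mean(log(.data$ratio))),
      mc_se_log = stats::sd(log(.data$ratio)) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  }
  out
}

#' Category switch tables for a batch of paired estimates
#'
#' Turns paired gold-standard/comparator results into frequency- or
#' evidence-category switch tables, one per comparator estimator.
#'
#' For `mode = "frequency"`, `pairs` needs columns `estimator`, `estimate`
#' (comparator AE probability) and `gold` (benchmark AE probability) — the
#' shape produced by [bias_vs_gold()]. For `mode = "evidence"`, `pairs`
#' needs per-AE relative effects with CIs: columns `estimator`, `estimate`,
#' `lower`, `upper` and `gold_estimate`, `gold_lower`, `gold_upper`;
#' optional logical `defined`/`gold_defined` columns mark exclusions, which
#' are dropped and counted in each table's `n_dropped` attribute.
#'
#' @param pairs A tibble of paired results (see Details).
#' @param mode `"frequency"` or `"evidence"`.
#' @return A named list of [switch_table()]s, one per comparator estimator.
#' @export
category_impact <- function(pairs, mode = c("frequency", "evidence")) {
  mode <- rlang::arg_match(mode)
  if (!"estimator" %in% names(pairs)) {
    abort("`pairs` needs an `estimator` column.")
  }
  split_by <- split(tibble::as_tibble(pairs), pairs$estimator)
  purrr::map(split_by, function(p) {
    if (mode == "frequency") {
      switch_table(frequency_category(p$gold), frequency_category(p$estimate))
    } else {
      defined <- (p[["defined"]] %||% TRUE) & (p[["gold_defined"]] %||% TRUE)
      gold <- comp <- factor(rep(NA, nrow(p)), levels = EVIDENCE_LEVELS, ordered = TRUE)
      if (any(defined)) {
        gold[defined] <- evidence_category(tibble::tibble(
          estimate = p$gold_estimate[defined], lower = p$gold_lower[defined],
          upper = p$gold_upper[defined]
        ))
        comp[defined] <- evidence_category(p[defined, c("estimate", "lower", "upper")])
      }
      switch_table(gold, comp)
    }
  })
}
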