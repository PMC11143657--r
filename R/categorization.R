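# Regulatory categorization: SmPC/CIOMS frequency classes for absolute AE
# risks, IQWiG-style evidence classes for relative effects, and
# estimator-vs-gold switch tables.

FREQUENCY_LEVELS <- c("very_rare", "rare", "uncommon", "common", "very_common")
EVIDENCE_LEVELS <- c("no_effect", "minor", "considerable", "major")

# All category thresholds in one place. Frequency classes use strict "<" at
# each upper edge with ">= 10%" closing the top class. The evidence rule's
# interval notation overlaps at its cut points; boundaries resolve toward the
# LESS severe class (e.g. an upper bound of exactly 0.9 is "minor", a lower
# bound of exactly 1.33 is "considerable").
CATEGORY_THRESHOLDS <- list(
  frequency = c(very_rare = 0.0001, rare = 0.001, uncommon = 0.01, common = 0.1),
  evidence_below = c(minor = 0.9, considerable = 0.75), # CI upper bound, effect < 1
  evidence_above = c(minor = 1.11, considerable = 1.33) # CI lower bound, effect > 1
)

#' SmPC/CIOMS frequency category of an AE probability
#'
#' Classifies an absolute AE risk into the five frequency classes used in
#' summaries of product characteristics: "very rare" (< 0.01%), "rare"
#' (< 0.1%), "uncommon" (< 1%), "common" (< 10%), and "very common"
#' (>= 10%).
#'
#' @param p Probability vector in \[0, 1\].
#' @return An ordered factor with levels `very_rare < rare < uncommon <
#'   common < very_common`.
#' @examples
#' frequency_category(c(0.092, 0.10, 0))
#' @export
frequency_category <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("Probabilities must lie in [0, 1] and be non-missing.")
  }
  cuts <- CATEGORY_THRESHOLDS$frequency
  idx <- findInterval(p, c(cuts, Inf)) + 1L # strict "<" at each upper edge
  factor(FREQUENCY_LEVELS[idx], levels = FREQUENCY_LEVELS, ordered = TRUE)
}

#' Evidence category of a relative effect
#'
#' Classifies a relative effect (risk ratio or hazard ratio) by its
#' confidence interval: "no effect" if 1 is inside the CI; otherwise, for an
#' effect above 1, by the lower CI bound (`<= 1.11` minor, `<= 1.33`
#' considerable, `> 1.33` major) and symmetrically, for an effect below 1,
#' by the upper bound (`>= 0.9` minor, `>= 0.75` considerable, `< 0.75`
#' major). Harm and benefit directions are treated alike. Boundary values
#' fall into the less severe class (see `CATEGORY_THRESHOLDS`).
#'
#' @param effects A `relative_effect` tibble (or any data frame with
#'   `estimate`, `lower`, `upper` columns and optionally `defined`).
#' @return An ordered factor with levels `no_effect < minor < considerable <
#'   major`, one per row.
#' @export
evidence_category <- function(effects) {
  if (!all(c("estimate", "lower", "upper") %in% names(effects))) {
    abort("`effects` needs columns `estimate`, `lower`, `upper`.")
  }
  if ("defined" %in% names(effects) && !all(effects$defined)) {
    abort("Cannot categorize undefined effects; filter on `defined` first (and report exclusions).")
  }
  if (any(is.na(effects$lower) | is.na(effects$upper))) {
    abort("Cannot categorize effects without confidence intervals.")
  }
  classify <- function(point, lower, upper) {
    if (lower <= 1 && upper >= 1) {
      return("no_effect")
    }
    th_b <- CATEGORY_THRESHOLDS$evidence_below
    th_a <- CATEGORY_THRESHOLDS$evidence_above
    if (point > 1) {
      if (lower <= th_a[["minor"]]) "minor"
      else if (lower <= th_a[["considerable"]]) "considerable"
      else "major"
    } else {
      if (upper >= th_b[["minor"]]) "minor"
      else if (upper >= th_b[["considerable"]]) "considerable"
      else "major"
    }
  }
  out <- mapply(classify, effects$estimate, effects$lower, effects$upper)
  factor(out, levels = EVIDENCE_LEVELS, ordered = TRUE)
}

#' Category switch table against a gold standard
#'
#' Cross-tabulates paired category assignments: rows are the gold-standard
#' categories, columns the comparator's. Diagonal entries are agreements;
#' off-diagonal entries are category switches induced by the comparator
#' estimator. Pairs where either entry is missing (e.g. from an undefined
#' effect) are dropped and counted in the `n_dropped` attribute.
#'
#' @param gold,comparator Factors (or vectors coercible to factors on the
#'   same level set) of equal length, pairing the same AEs in the same
#'   order.
#' @return A `switch_table`: an integer matrix (gold in rows) with
#'   `n_dropped` attribute, plus [tidy()] and [autoplot()] methods.
#' @export
switch_table <- function(gold, comparator) {
  if (length(gold) != length(comparator)) {
    abort("`gold` and `comparator` must pair the same AEs (equal length).")
  }
  levels_ <- levels(gold) %||% levels(comparator) %||% sort(unique(c(gold, comparator)))
  gold <- factor(gold, levels = levels_, ordered = TRUE)
  comparator <- factor(comparator, levels = levels_, ordered = TRUE)
  keep <- !is.na(gold) & !is.na(comparator)
  tab <- table(gold = gold[keep], comparator = comparator[keep])
  out <- unclass(as.matrix(tab))
  structure(out,
    class = c("switch_table", "matrix"),
    n_dropped = sum(!keep)
  )
}

#' @export
print.switch_table <- function(x, ...) {
  cat("<switch_table> gold standard in rows, comparator in columns\n")
  print(matrix(x, nrow(x), ncol(x), dimnames = dimnames(x)))
  dropped <- attr(x, "n_dropped")
  if (dropped > 0) cat(sprintf("  (%d undefined pair(s) dropped)\n", dropped))
  cat(sprintf(
    "  agreement: %d / %d\n", sum(diag(x)), sum(x)
  ))
  invisible(x)
}

#' @export
tidy.switch_table <- function(x, ...) {
  out <- tibble::as_tibble(as.table(matrix(x, nrow(x), ncol(x),
    dimnames = dimnames(x)
  )), .name_repair = "minimal")
  names(out) <- c("gold", "comparator", "n")
  out$n <- as.integer(out$n)
  out
}

#' Upgrade/downgrade balance of a switch table
#'
#' Counts how many classified AEs the comparator places above
#' (`upgrades`) or below (`downgrades`) the gold standard's category.
#'
#' @param x A [switch_table()].
#' @return Named integer vector `c(upgrades, downgrades)`.
#' @export
switch_balance <- function(x) {
  idx <- which(matrix(TRUE, nrow(x), ncol(x)), arr.ind = TRUE)
  up <- sum(x[idx[idx[, "col"] > idx[, "row"], , drop = FALSE]])
  down <- sum(x[idx[idx[, "col"] < idx[, "row"], , drop = FALSE]])
  c(upgrades = up, downgrades = down)
}
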