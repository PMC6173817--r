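# Evaluation of traffic-light tiers against binary adverse outcomes, and
# 2x2 odds-ratio machinery for pre/post intervention comparisons.

#' Tier-by-outcome contingency table
#'
#' Classifies every reading in a cohort with the early warning system and
#' tabulates alert colour against a named binary outcome.
#'
#' @param cohort Data frame with reading columns (`sbp`, `dbp`, `pulse`,
#'   optional identifiers) plus one or more logical/0-1 outcome columns.
#' @param cfg A [vsa_thresholds()] configuration.
#' @param outcome Name of the outcome column to tabulate.
#' @return A 3 x 2 integer matrix of class `tier_outcome_table` with rows
#'   `green`, `yellow`, `red` and columns `yes`, `no`; the outcome name is
#'   kept in `attr(, "outcome")`.
#' @export
#' @examples
#' cohort <- data.frame(sbp = c(120, 165), dbp = c(70, 112),
#'                      pulse = c(80, 90), icu = c(FALSE, TRUE))
#' tier_outcome_table(cohort, vsa_thresholds(), "icu")
tier_outcome_table <- function(cohort, cfg = vsa_thresholds(), outcome) {
  assert_thresholds(cfg)
  if (!is.character(outcome) || length(outcome) != 1L)
    stop("'outcome' must be a single column name", call. = FALSE)
  if (!outcome %in% names(cohort))
    stop(sprintf("unknown outcome column '%s'", outcome), call. = FALSE)
  y <- cohort[[outcome]]
  if (is.numeric(y)) {
    if (!all(y %in% c(0, 1)))
      stop(sprintf("outcome '%s' must be logical or 0/1", outcome),
           call. = FALSE)
    y <- y == 1
  }
  if (!is.logical(y) || anyNA(y))
    stop(sprintf("outcome '%s' must be logical or 0/1 without missing values",
                 outcome), call. = FALSE)
  colour <- vsa_alert(cohort, cfg)$colour
  tab <- table(colour = colour, outcome = factor(ifelse(y, "yes", "no"),
                                                 levels = c("yes", "no")))
  m <- matrix(as.integer(tab), nrow = 3,
              dimnames = list(tier = TIER_LEVELS, outcome = c("yes", "no")))
  structure(m, class = c("tier_outcome_table", "matrix"), outcome = outcome)
}

#' Per-tier risk, risk ratios and monotone trend
#'
#' Event risk within each alert tier, risk ratio of each tier versus
#' green, and whether risk is non-decreasing with worsening tier — the
#' pattern expected of a well-calibrated early warning threshold set.
#'
#' Tiers with no observations get `NA` risk (undefined, not zero); the
#' trend flag ignores undefined tiers.
#'
#' @param table A `tier_outcome_table` from [tier_outcome_table()].
#' @return List with `risk` (named per-tier), `risk_ratio` (vs green),
#'   `monotone_trend` (logical) and per-tier `n`.
#' @export
tier_risk_metrics <- function(table) {
  if (!inherits(table, "tier_outcome_table"))
    stop("'table' must come from tier_outcome_table()", call. = FALSE)
  n <- table[, "yes"] + table[, "no"]
  risk <- ifelse(n > 0, table[, "yes"] / n, NA_real_)
  names(risk) <- rownames(table)
  if (is.na(risk["green"]) )
    stop("green tier has no observations; risk ratios undefined",
         call. = FALSE)
  rr <- risk / risk[["green"]]
  defined <- risk[!is.na(risk)]
  trend <- all(diff(defined) >= 0)
  list(risk = risk, risk_ratio = rr, monotone_trend = trend, n = n)
}

#' Diagnostic accuracy at an alert threshold
#'
#' Collapses the tier-by-outcome table to a 2x2 by dichotomising at
#' "yellow or worse" (default) or "red", and reports the standard
#' diagnostic metrics. Ratios with zero denominators are returned as `NA`
#' and listed in `undefined`.
#'
#' @param table A `tier_outcome_table`.
#' @param alert_at `"yellow"` (alert = yellow or red) or `"red"`.
#' @return List with `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `lr_positive`, `lr_negative`, the collapsed 2x2 counts
#'   (`a`, `b`, `c`, `d`), and `undefined` (character vector of metrics
#'   with zero denominators).
#' @export
#' @examples
#' # collapsed counts a=30, b=70, c=10, d=190 give sens 0.75, spec 0.731
diagnostic_metrics <- function(table, alert_at = c("yellow", "red")) {
  alert_at <- match.arg(alert_at)
  if (!inherits(table, "tier_outcome_table"))
    stop("'table' must come from tier_outcome_table()", call. = FALSE)
  pos <- if (alert_at == "yellow") c("yellow", "red") else "red"
  neg <- setdiff(TIER_LEVELS, pos)
  a <- sum(table[pos, "yes"]); b <- sum(table[pos, "no"])
  cc <- sum(table[neg, "yes"]); d <- sum(table[neg, "no"])
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- ratio(a, a + cc)
  spec <- ratio(d, b + d)
  out <- list(
    sensitivity = sens,
    specificity = spec,
    ppv = ratio(a, a + b),
    npv = ratio(d, cc + d),
    lr_positive = if (!is.na(sens) && !is.na(spec) && spec < 1)
      sens / (1 - spec) else NA_real_,
    lr_negative = if (!is.na(sens) && !is.na(spec) && spec > 0)
      (1 - sens) / spec else NA_real_,
    a = a, b = b, c = cc, d = d
  )
  out$undefined <- names(out)[seq_len(6)][vapply(out[seq_len(6)], is.na,
                                                 logical(1))]
  out
}

#' Odds ratio with Woolf confidence interval
#'
#' Crude odds ratio ad/bc from a 2x2 table of counts
#' (a = exposed events, b = exposed non-events, c = unexposed events,
#' d = unexposed non-events), with the Woolf log-normal 95% confidence
#' interval `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` and a
#' two-sided p-value from the normal approximation on the log odds ratio.
#'
#' With `correction = "haldane"`, 0.5 is added to every cell whenever any
#' cell is zero (Haldane–Anscombe); with `"none"`, zero cells are an
#' error. The estimator is crude (unadjusted); adjusted or cluster-aware
#' models are out of scope.
#'
#' @param a,b,c,d Non-negative integer counts.
#' @param correction `"none"` (default) or `"haldane"`.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `or`, `ci_lower`, `ci_upper`, `p_value`, `log_or`,
#'   `se_log_or`, `correction_applied`.
#' @export
#' @examples
#' odds_ratio(92, 455, 174, 520)$or   # 0.6043
odds_ratio <- function(a, b, c, d, correction = c("none", "haldane"),
                       conf_level = 0.95) {
  correction <- match.arg(correction)
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0) ||
      any(cells != round(cells)))
    stop("cells must be non-negative integer counts", call. = FALSE)
  if (sum(cells) == 0) stop("empty table", call. = FALSE)
  applied <- FALSE
  if (any(cells == 0)) {
    if (correction == "none")
      stop("zero cell; use correction = \"haldane\" or supply counts > 0",
           call. = FALSE)
    cells <- cells + 0.5
    applied <- TRUE
  }
  or <- (cells["a"] * cells["d"]) / (cells["b"] * cells["c"])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  lo <- exp(log(or) - z * se)
  hi <- exp(log(or) + z * se)
  p <- 2 * stats::pnorm(-abs(log(or)) / se)
  list(or = unname(or), ci_lower = unname(lo), ci_upper = unname(hi),
       p_value = unname(p), log_or = unname(log(or)),
       se_log_or = unname(se), correction_applied = applied)
}

#' Pre/post intervention proportion comparison
#'
#' Compares the proportion with a binary indicator (for instance "blood
#' pressure never measured in this pregnancy") before and after an
#' intervention: per-phase proportions, their absolute difference
#' (post minus pre), and the crude odds ratio of the indicator in the
#' post phase relative to the pre phase with its Woolf interval.
#'
#' @param pre,post Either logical vectors of per-woman indicators, or
#'   lists `list(events =, n =)` of summary counts.
#' @param correction Zero-cell handling passed to [odds_ratio()].
#' @return List with `p_pre`, `p_post`, `n_pre`, `n_post`,
#'   `abs_difference` and `or` (the [odds_ratio()] result, post as
#'   exposed).
#' @export
#' @examples
#' prepost_analysis(list(events = 100, n = 200),
#'                  list(events = 50, n = 200))$or$or  # 1/3
prepost_analysis <- function(pre, post, correction = c("none", "haldane")) {
  correction <- match.arg(correction)
  summarise <- function(x, nm) {
    if (is.logical(x)) {
      if (anyNA(x)) stop(nm, " indicator has missing values", call. = FALSE)
      list(events = sum(x), n = length(x))
    } else if (is.list(x) && all(c("events", "n") %in% names(x))) {
      if (x$events < 0 || x$n <= 0 || x$events > x$n)
        stop(nm, " counts invalid", call. = FALSE)
      x[c("events", "n")]
    } else stop(nm, " must be a logical vector or list(events =, n =)",
                call. = FALSE)
  }
  s_pre <- summarise(pre, "pre"); s_post <- summarise(post, "post")
  or <- odds_ratio(s_post$events, s_post$n - s_post$events,
                   s_pre$events, s_pre$n - s_pre$events,
                   correction = correction)
  list(
    p_pre = s_pre$events / s_pre$n,
    p_post = s_post$events / s_post$n,
    n_pre = s_pre$n, n_post = s_post$n,
    abs_difference = s_post$events / s_post$n - s_pre$events / s_pre$n,
    or = or
  )
}
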