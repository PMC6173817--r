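# Paired device-vs-reference validation statistics: pairing schemes for
# alternating same-arm measurement sequences, mean/SD difference analysis,
# ISO pass/fail bounds and BHS cumulative-percentage grading.

#' BHS cumulative-percentage grade table
#'
#' Grading criteria of the British Hypertension Society device-validation
#' protocol: a device earns a grade when the cumulative percentages of
#' absolute device-minus-reference differences within 5, 10 and 15 mm Hg
#' all reach that grade's requirements. Grade A requires 60/85/95, B
#' 50/75/90, C 40/65/85; anything worse is D.
#'
#' @return Data frame with columns `grade`, `pct_within_5`, `pct_within_10`,
#'   `pct_within_15`.
#' @export
#' @examples
#' bhs_grade_table()
bhs_grade_table <- function() {
  data.frame(
    grade = c("A", "B", "C"),
    pct_within_5 = c(60, 50, 40),
    pct_within_10 = c(85, 75, 65),
    pct_within_15 = c(95, 90, 85),
    stringsAsFactors = FALSE
  )
}

# A measurement sequence table holds one measurement per row:
# subject_id, position (1-based), source ("reference"/"device"),
# sbp, dbp, plus optional covariates arm_circumference and cuff.
assert_sequence_table <- function(x) {
  if (!is.data.frame(x))
    stop("measurement sequences must be a data frame", call. = FALSE)
  need <- c("subject_id", "position", "source", "sbp", "dbp")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("sequence table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(x$source %in% c("reference", "device")))
    stop("source must be 'reference' or 'device'", call. = FALSE)
  invisible(x)
}

#' Build device-vs-reference comparison pairs
#'
#' Turns alternating same-arm measurement sequences (reference, device,
#' reference, ...) into comparison pairs. Two schemes are offered:
#' \describe{
#'   \item{`flanking_mean`}{each device measurement is compared with the
#'     mean of the two reference measurements surrounding it — the standard
#'     convention for sequential same-arm validation, which cancels the
#'     slow drift of true pressure over the session. Requires an odd-length
#'     sequence of at least 3 ending on a reference; a 7-measurement
#'     sequence yields 3 pairs.}
#'   \item{`same_index`}{each device measurement is compared with the
#'     reference immediately preceding it; offered for sensitivity
#'     analysis, and the natural scheme for simultaneous two-measurement
#'     (reference, device) protocols.}
#' }
#'
#' @param sequences Data frame with one measurement per row: `subject_id`,
#'   `position`, `source` (`"reference"`/`"device"`), `sbp`, `dbp`, and
#'   optional covariates `arm_circumference` (cm) and `cuff`.
#' @param scheme Pairing scheme, `"flanking_mean"` (default) or
#'   `"same_index"`.
#' @return Data frame of comparison pairs: `subject_id`, `device_sbp`,
#'   `device_dbp`, `reference_sbp`, `reference_dbp`, `diff_sbp`,
#'   `diff_dbp` (device minus reference, mm Hg) and carried covariates.
#' @export
#' @examples
#' seqs <- data.frame(
#'   subject_id = "s1", position = 1:7,
#'   source = rep(c("reference", "device"), length.out = 7),
#'   sbp = c(100, 102, 104, 106, 108, 110, 112),
#'   dbp = c(60, 62, 64, 66, 68, 70, 72))
#' build_comparison_pairs(seqs, "flanking_mean")$diff_sbp  # 0 0 0
#' build_comparison_pairs(seqs, "same_index")$diff_sbp     # 2 2 2
build_comparison_pairs <- function(sequences,
                                   scheme = c("flanking_mean",
                                              "same_index")) {
  scheme <- match.arg(scheme)
  assert_sequence_table(sequences)
  out <- lapply(split(sequences, sequences$subject_id), function(s) {
    s <- s[order(s$position), , drop = FALSE]
    m <- nrow(s)
    expected <- rep(c("reference", "device"), length.out = m)
    if (!identical(as.character(s$source), expected))
      stop(sprintf(
        "subject '%s': measurements must alternate starting with reference",
        s$subject_id[1]), call. = FALSE)
    if (scheme == "flanking_mean") {
      if (m < 3L || m %% 2L == 0L)
        stop(sprintf(
          "subject '%s': flanking_mean needs an odd-length sequence (>= 3) ending on a reference measurement, got %d",
          s$subject_id[1], m), call. = FALSE)
      dev_idx <- seq(2L, m - 1L, by = 2L)
      ref_sbp <- (s$sbp[dev_idx - 1L] + s$sbp[dev_idx + 1L]) / 2
      ref_dbp <- (s$dbp[dev_idx - 1L] + s$dbp[dev_idx + 1L]) / 2
    } else {
      if (m < 2L)
        stop(sprintf("subject '%s': need at least one reference-device pair",
                     s$subject_id[1]), call. = FALSE)
      dev_idx <- seq(2L, m, by = 2L)
      ref_sbp <- s$sbp[dev_idx - 1L]
      ref_dbp <- s$dbp[dev_idx - 1L]
    }
    pairs <- data.frame(
      subject_id = s$subject_id[1],
      device_sbp = s$sbp[dev_idx], device_dbp = s$dbp[dev_idx],
      reference_sbp = ref_sbp, reference_dbp = ref_dbp,
      stringsAsFactors = FALSE
    )
    for (cov in intersect(c("arm_circumference", "cuff"), names(s)))
      pairs[[cov]] <- s[[cov]][1]
    pairs
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty_pairs())
  out$diff_sbp <- out$device_sbp - out$reference_sbp
  out$diff_dbp <- out$device_dbp - out$reference_dbp
  rownames(out) <- NULL
  out
}

empty_pairs <- function() {
  data.frame(subject_id = character(0), device_sbp = numeric(0),
             device_dbp = numeric(0), reference_sbp = numeric(0),
             reference_dbp = numeric(0), diff_sbp = numeric(0),
             diff_dbp = numeric(0), stringsAsFactors = FALSE)
}

#' Mean and SD of device-minus-reference differences
#'
#' The core accuracy statistic of paired validation: arithmetic mean and
#' sample standard deviation (n - 1 denominator) of the differences, per
#' pressure component, optionally restricted to a covariate stratum.
#'
#' An empty selection is reported explicitly (`n_pairs = 0`, `NA`
#' statistics) rather than as zeros.
#'
#' @param pairs Comparison pairs from [build_comparison_pairs()].
#' @param stratum Optional logical vector (or expression evaluated in
#'   `pairs`) selecting a subset, e.g. an arm-circumference band.
#' @return An object of class `diff_stats`: list with `n_pairs`,
#'   `mean_diff_sbp`, `sd_diff_sbp`, `mean_diff_dbp`, `sd_diff_dbp`
#'   (mm Hg).
#' @export
#' @examples
#' p <- data.frame(diff_sbp = c(2, 4, 6), diff_dbp = c(0, 0, 0))
#' difference_stats(p)
difference_stats <- function(pairs, stratum = NULL) {
  if (!is.data.frame(pairs) ||
      !all(c("diff_sbp", "diff_dbp") %in% names(pairs)))
    stop("'pairs' must have diff_sbp and diff_dbp columns", call. = FALSE)
  if (!is.null(stratum)) {
    if (!is.logical(stratum) || length(stratum) != nrow(pairs))
      stop("'stratum' must be a logical vector over the pairs",
           call. = FALSE)
    pairs <- pairs[stratum & !is.na(stratum), , drop = FALSE]
  }
  n <- nrow(pairs)
  st <- list(
    n_pairs = n,
    mean_diff_sbp = if (n) mean(pairs$diff_sbp) else NA_real_,
    sd_diff_sbp = if (n >= 2) stats::sd(pairs$diff_sbp) else NA_real_,
    mean_diff_dbp = if (n) mean(pairs$diff_dbp) else NA_real_,
    sd_diff_dbp = if (n >= 2) stats::sd(pairs$diff_dbp) else NA_real_
  )
  structure(st, class = "diff_stats")
}

#' @export
print.diff_stats <- function(x, ...) {
  cat(sprintf("Paired differences (device - reference), n = %d\n",
              x$n_pairs))
  cat(sprintf("  SBP: mean %.2f (SD %.2f) mm Hg\n",
              x$mean_diff_sbp, x$sd_diff_sbp))
  cat(sprintf("  DBP: mean %.2f (SD %.2f) mm Hg\n",
              x$mean_diff_dbp, x$sd_diff_dbp))
  invisible(x)
}

#' ISO accuracy assessment
#'
#' Applies the ISO sphygmomanometer accuracy criterion to paired-difference
#' statistics: a component passes when the absolute mean difference is at
#' most `mean_bound` (default 5 mm Hg) and the standard deviation is at
#' most `sd_bound` (default 8 mm Hg); both boundaries inclusive. The device
#' passes overall when both components pass.
#'
#' @param stats A `diff_stats` object from [difference_stats()].
#' @param mean_bound Maximum allowed |mean difference|, mm Hg.
#' @param sd_bound Maximum allowed SD of differences, mm Hg.
#' @return List with logical `sbp_pass`, `dbp_pass`, `pass`, and the bounds
#'   used.
#' @export
#' @examples
#' p <- data.frame(diff_sbp = c(2, 4, 6), diff_dbp = c(0, 1, -1))
#' iso_assess(difference_stats(p))
iso_assess <- function(stats, mean_bound = 5, sd_bound = 8) {
  if (!inherits(stats, "diff_stats"))
    stop("'stats' must come from difference_stats()", call. = FALSE)
  if (stats$n_pairs < 2)
    stop("ISO assessment needs at least 2 pairs", call. = FALSE)
  comp <- function(m, s) abs(m) <= mean_bound && s <= sd_bound
  sbp_pass <- comp(stats$mean_diff_sbp, stats$sd_diff_sbp)
  dbp_pass <- comp(stats$mean_diff_dbp, stats$sd_diff_dbp)
  list(sbp_pass = sbp_pass, dbp_pass = dbp_pass,
       pass = sbp_pass && dbp_pass,
       mean_bound = mean_bound, sd_bound = sd_bound)
}

#' Cumulative percentages of absolute differences
#'
#' Percentage of absolute differences within 5, 10 and 15 mm Hg — the
#' quantities graded by the BHS protocol. Non-decreasing by construction.
#'
#' @param diffs Numeric vector of device-minus-reference differences.
#' @return Named numeric vector `within_5`, `within_10`, `within_15` (%).
#' @export
cumulative_within <- function(diffs) {
  if (!length(diffs)) stop("no differences supplied", call. = FALSE)
  a <- abs(diffs)
  c(within_5 = 100 * mean(a <= 5),
    within_10 = 100 * mean(a <= 10),
    within_15 = 100 * mean(a <= 15))
}

#' BHS grade of a set of comparison pairs
#'
#' Awards the highest grade whose three cumulative-percentage requirements
#' (within 5, 10 and 15 mm Hg) are all met; `"D"` when none is.
#'
#' @param pairs Comparison pairs from [build_comparison_pairs()], or a
#'   numeric vector of differences for a single component.
#' @param grade_table Criteria table as from [bhs_grade_table()].
#' @return For pairs, a named character vector `c(sbp =, dbp =)`; for a
#'   numeric vector, a single grade.
#' @export
#' @examples
#' bhs_grade(rep(0, 10))       # "A"
#' bhs_grade(rep(20, 10))      # "D"
bhs_grade <- function(pairs, grade_table = bhs_grade_table()) {
  check_grade_table(grade_table)
  grade_one <- function(diffs) {
    cw <- cumulative_within(diffs)
    for (i in seq_len(nrow(grade_table))) {
      g <- grade_table[i, ]
      if (cw["within_5"] >= g$pct_within_5 &&
          cw["within_10"] >= g$pct_within_10 &&
          cw["within_15"] >= g$pct_within_15)
        return(g$grade)
    }
    "D"
  }
  if (is.numeric(pairs)) return(grade_one(pairs))
  if (!is.data.frame(pairs) ||
      !all(c("diff_sbp", "diff_dbp") %in% names(pairs)))
    stop("'pairs' must be a pairs data frame or a numeric vector of diffs",
         call. = FALSE)
  if (!nrow(pairs)) stop("no pairs supplied", call. = FALSE)
  c(sbp = grade_one(pairs$diff_sbp), dbp = grade_one(pairs$diff_dbp))
}

check_grade_table <- function(gt) {
  need <- c("grade", "pct_within_5", "pct_within_10", "pct_within_15")
  if (!is.data.frame(gt) || !all(need %in% names(gt)) || !nrow(gt))
    stop("grade table must have columns grade, pct_within_5/10/15",
         call. = FALSE)
  pc <- as.matrix(gt[, need[-1]])
  if (any(!is.finite(pc)) || any(pc < 0) || any(pc > 100))
    stop("grade-table percentages must lie in [0, 100]", call. = FALSE)
  # rows must be ordered strictest first so "highest grade" is well defined
  if (nrow(gt) > 1 && any(diff(gt$pct_within_5) > 0))
    stop("grade table rows must be ordered from strictest to most lenient",
         call. = FALSE)
  invisible(gt)
}

#' Run a full device-validation analysis
#'
#' Pipeline over a paired study: build comparison pairs, compute
#' difference statistics, apply the ISO bounds and BHS grading — overall
#' and within arm-circumference strata. Deterministic given its inputs.
#'
#' @param sequences Measurement-sequence table (see
#'   [build_comparison_pairs()]).
#' @param scheme Pairing scheme passed to [build_comparison_pairs()].
#' @param mean_bound,sd_bound ISO bounds, mm Hg (defaults 5 and 8).
#' @param grade_table BHS criteria table, default [bhs_grade_table()].
#' @param strata Named list of arm-circumference bands (closed intervals,
#'   cm) defining sub-reports; default the 22–32 and 33–42 cm bands. Set to
#'   `NULL` (or omit `arm_circumference`) to skip stratification.
#' @return An object of class `validation_report`: list with `n_pairs`,
#'   `stats` (`diff_stats`), `iso` (from [iso_assess()]), `bhs` (grades),
#'   `cumulative` (per-component cumulative percentages) and `strata`, a
#'   named list of sub-reports of the same shape.
#' @export
run_validation <- function(sequences,
                           scheme = c("flanking_mean", "same_index"),
                           mean_bound = 5, sd_bound = 8,
                           grade_table = bhs_grade_table(),
                           strata = list(`22-32 cm` = c(22, 32),
                                         `33-42 cm` = c(33, 42))) {
  scheme <- match.arg(scheme)
  pairs <- build_comparison_pairs(sequences, scheme)
  report_of <- function(p) {
    st <- difference_stats(p)
    list(
      n_pairs = st$n_pairs,
      stats = st,
      iso = if (st$n_pairs >= 2) iso_assess(st, mean_bound, sd_bound),
      bhs = if (st$n_pairs >= 1) bhs_grade(p, grade_table),
      cumulative = if (st$n_pairs >= 1)
        list(sbp = cumulative_within(p$diff_sbp),
             dbp = cumulative_within(p$diff_dbp))
    )
  }
  rep_all <- report_of(pairs)
  rep_all$scheme <- scheme
  rep_all$strata <- list()
  if (!is.null(strata) && "arm_circumference" %in% names(pairs)) {
    for (nm in names(strata)) {
      band <- strata[[nm]]
      sel <- pairs$arm_circumference >= band[1] &
        pairs$arm_circumference <= band[2]
      sub <- pairs[sel & !is.na(sel), , drop = FALSE]
      rep_all$strata[[nm]] <-
        if (nrow(sub)) report_of(sub) else list(n_pairs = 0L)
    }
  }
  structure(rep_all, class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Device validation report (%s pairing), %d pairs\n",
              x$scheme, x$n_pairs))
  print(x$stats)
  if (!is.null(x$iso))
    cat(sprintf("  ISO (|mean| <= %g, SD <= %g): %s\n", x$iso$mean_bound,
                x$iso$sd_bound, if (x$iso$pass) "PASS" else "FAIL"))
  if (!is.null(x$bhs))
    cat(sprintf("  BHS grades: SBP %s, DBP %s\n", x$bhs[["sbp"]],
                x$bhs[["dbp"]]))
  for (nm in names(x$strata)) {
    s <- x$strata[[nm]]
    if (s$n_pairs == 0) { cat(sprintf("  stratum %s: empty\n", nm)); next }
    cat(sprintf("  stratum %s: n=%d, SBP mean %.2f (SD %.2f), ISO %s\n",
                nm, s$n_pairs, s$stats$mean_diff_sbp, s$stats$sd_diff_sbp,
                if (isTRUE(s$iso$pass)) "PASS" else "FAIL"))
  }
  invisible(x)
}
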