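# Plausibility windows for a vital-signs reading (mm Hg, beats/min).
# Values outside are treated as sensor/transcription error and rejected.
SBP_WINDOW <- c(40, 300)
DBP_WINDOW <- c(20, 200)
PULSE_WINDOW <- c(20, 250)

READING_CONTEXTS <- c("antenatal", "intrapartum", "postnatal", "unknown")

#' Shock Index
#'
#' The Shock Index (SI) is pulse rate divided by systolic blood pressure.
#' Values around 0.7 are typical in pregnancy; elevated values flag
#' haemodynamic compromise from haemorrhage or sepsis earlier than either
#' vital sign alone.
#'
#' The unrounded ratio is returned; use [si_display()] when formatting for
#' display so classification is never affected by rounding.
#'
#' @param pulse Pulse rate, beats/min. Vectorised.
#' @param sbp Systolic blood pressure, mm Hg. Vectorised.
#' @return Numeric vector of Shock Index values (dimensionless).
#' @export
#' @examples
#' shock_index(90, 100)   # 0.9
#' shock_index(120, 80)   # 1.5
shock_index <- function(pulse, sbp) {
  if (!is.numeric(pulse) || !is.numeric(sbp))
    stop("pulse and sbp must be numeric", call. = FALSE)
  bad <- !is.finite(pulse) | !is.finite(sbp) | pulse <= 0 | sbp <= 0
  if (any(bad))
    stop("pulse and sbp must be positive and finite", call. = FALSE)
  pulse / sbp
}

#' Format a Shock Index value for display
#'
#' Rounds to a fixed number of decimals using banker's (round-half-even)
#' rounding. Rounding is a display concern only: tier classification always
#' uses the exact ratio.
#'
#' @param value Shock Index value(s) from [shock_index()].
#' @param digits Decimals to keep (default 2).
#' @return Numeric vector rounded for reporting.
#' @export
si_display <- function(value, digits = 2) {
  round(value, digits = digits)
}

# Tier from a value and its two thresholds, honouring the boundary
# convention. Vectorised over `x`.
tier_from_cutoffs <- function(x, yellow, red, inclusive) {
  if (inclusive) {
    ifelse(x >= red, "red", ifelse(x >= yellow, "yellow", "green"))
  } else {
    ifelse(x > red, "red", ifelse(x > yellow, "yellow", "green"))
  }
}

#' Hypertension tier of a reading
#'
#' A reading is red if either pressure reaches the red threshold, else
#' yellow if either reaches the yellow threshold, else green. Pulse never
#' influences the hypertension tier.
#'
#' @param sbp,dbp Systolic/diastolic blood pressure, mm Hg. Vectorised.
#' @param cfg A [vsa_thresholds()] configuration.
#' @return Ordered factor with levels green < yellow < red.
#' @export
#' @examples
#' cfg <- vsa_thresholds()
#' classify_hypertension(c(120, 145, 150), c(70, 88, 112), cfg)
classify_hypertension <- function(sbp, dbp, cfg = vsa_thresholds()) {
  assert_thresholds(cfg)
  check_window(sbp, SBP_WINDOW, "sbp")
  check_window(dbp, DBP_WINDOW, "dbp")
  inc <- cfg$inclusive_boundaries
  sev_sbp <- tier_severity(tier_from_cutoffs(sbp, cfg$hyp_yellow_sbp,
                                             cfg$hyp_red_sbp, inc))
  sev_dbp <- tier_severity(tier_from_cutoffs(dbp, cfg$hyp_yellow_dbp,
                                             cfg$hyp_red_dbp, inc))
  tier_factor(TIER_LEVELS[pmax(sev_sbp, sev_dbp)])
}

#' Shock tier of a reading
#'
#' Compares the exact Shock Index (pulse/SBP) to the configured SI
#' thresholds under the same boundary convention as the hypertension tiers.
#'
#' @param pulse Pulse rate, beats/min. Vectorised.
#' @param sbp Systolic blood pressure, mm Hg. Vectorised.
#' @param cfg A [vsa_thresholds()] configuration.
#' @return Ordered factor with levels green < yellow < red.
#' @export
#' @examples
#' cfg <- vsa_thresholds()
#' classify_shock(c(80, 108, 136), c(120, 120, 80), cfg)
classify_shock <- function(pulse, sbp, cfg = vsa_thresholds()) {
  assert_thresholds(cfg)
  check_window(pulse, PULSE_WINDOW, "pulse")
  check_window(sbp, SBP_WINDOW, "sbp")
  si <- shock_index(pulse, sbp)
  tier_factor(tier_from_cutoffs(si, cfg$si_yellow, cfg$si_red,
                                cfg$inclusive_boundaries))
}

#' Traffic-light alert for vital-sign readings
#'
#' Combines the hypertension and shock tiers into the device's alert. The
#' alert colour is the more severe of the two tiers. Shock is prioritised:
#' whenever the shock tier is yellow or worse the alerting condition is
#' reported as shock and the display is the flashing down arrow, even if
#' the hypertension tier is the more severe of the two; hypertension-only
#' alerts show the constant up arrow. Both component tiers are retained so
#' no information is lost by the prioritisation.
#'
#' @param readings A data frame with numeric columns `sbp`, `dbp`, `pulse`
#'   (and any others, carried through unchanged), or a single reading given
#'   as a named list.
#' @param cfg A [vsa_thresholds()] configuration.
#' @return A data frame with one row per reading: the input identifier
#'   columns (if present), `shock_index`, `hypertension_tier`, `shock_tier`,
#'   `colour`, `condition` (one of `"none"`, `"hypertension"`, `"shock"`)
#'   and `display`.
#' @export
#' @examples
#' cfg <- vsa_thresholds()
#' vsa_alert(data.frame(sbp = c(162, 100, 118), dbp = c(95, 60, 75),
#'                      pulse = c(70, 95, 72)), cfg)
vsa_alert <- function(readings, cfg = vsa_thresholds()) {
  assert_thresholds(cfg)
  if (!is.data.frame(readings)) readings <- as.data.frame(readings)
  need <- c("sbp", "dbp", "pulse")
  miss <- setdiff(need, names(readings))
  if (length(miss))
    stop("readings lack required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  n <- nrow(readings)
  hyp <- classify_hypertension(readings$sbp, readings$dbp, cfg)
  shk <- classify_shock(readings$pulse, readings$sbp, cfg)
  colour <- tier_factor(TIER_LEVELS[pmax(tier_severity(hyp),
                                         tier_severity(shk))])
  condition <- ifelse(tier_severity(shk) >= 2L, "shock",
                      ifelse(tier_severity(hyp) >= 2L, "hypertension",
                             "none"))
  display <- unname(cfg$display_map[condition])
  id_cols <- intersect(c("subject_id", "timestamp", "context"),
                       names(readings))
  out <- cbind(
    readings[, id_cols, drop = FALSE],
    data.frame(
      sbp = readings$sbp, dbp = readings$dbp, pulse = readings$pulse,
      shock_index = shock_index(readings$pulse, readings$sbp),
      hypertension_tier = hyp,
      shock_tier = shk,
      colour = colour,
      condition = factor(condition,
                         levels = c("none", "hypertension", "shock")),
      display = display,
      stringsAsFactors = FALSE
    )
  )
  rownames(out) <- NULL
  out
}

check_window <- function(x, window, nm) {
  if (!is.numeric(x))
    stop(sprintf("'%s' must be numeric", nm), call. = FALSE)
  bad <- !is.finite(x) | x < window[1] | x > window[2]
  if (any(bad))
    stop(sprintf("'%s' outside plausibility window [%g, %g] at position %d",
                 nm, window[1], window[2], which(bad)[1]), call. = FALSE)
  invisible(x)
}

#' Validate raw vital-sign records
#'
#' Screens raw records against the plausibility invariants before
#' classification: SBP in [40, 300] mm Hg, DBP in [20, 200] mm Hg, pulse in
#' [20, 250] beats/min, SBP strictly above DBP, and a recognised context.
#' Rather than erroring, each failing row is returned in a rejection report
#' naming the first violated invariant, so a file ingest can continue past
#' bad rows.
#'
#' @param records Data frame of raw records with at least `sbp`, `dbp`,
#'   `pulse`; optional `subject_id`, `timestamp`, `context`.
#' @return A list with class `reading_validation`:
#'   \describe{
#'     \item{accepted}{data frame of valid readings (original columns,
#'       `context` normalised, `subject_id` added if absent)}
#'     \item{rejected}{data frame with `row` (input row number) and
#'       `reason` (machine-readable code) plus the offending values}
#'   }
#' @export
#' @examples
#' validate_readings(data.frame(sbp = c(120, 80), dbp = c(80, 90),
#'                              pulse = c(76, 76)))
validate_readings <- function(records) {
  if (!is.data.frame(records)) records <- as.data.frame(records)
  need <- c("sbp", "dbp", "pulse")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records lack required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  n <- nrow(records)
  if (!"subject_id" %in% names(records))
    records$subject_id <- if (n) sprintf("row%d", seq_len(n)) else character(0)
  if (!"context" %in% names(records)) records$context <- "unknown"
  records$context <- as.character(records$context)
  records$context[is.na(records$context) | records$context == ""] <- "unknown"

  num <- function(col) suppressWarnings(as.numeric(records[[col]]))
  sbp <- num("sbp"); dbp <- num("dbp"); pulse <- num("pulse")

  reason <- rep(NA_character_, n)
  flag <- function(cond, code) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- code
  }
  flag(is.na(sbp) | is.na(dbp) | is.na(pulse), "missing_value")
  flag(sbp < SBP_WINDOW[1] | sbp > SBP_WINDOW[2], "sbp_window")
  flag(dbp < DBP_WINDOW[1] | dbp > DBP_WINDOW[2], "dbp_window")
  flag(pulse < PULSE_WINDOW[1] | pulse > PULSE_WINDOW[2], "pulse_window")
  flag(sbp <= dbp, "sbp_not_above_dbp")
  flag(!(records$context %in% READING_CONTEXTS), "unknown_context")

  ok <- is.na(reason)
  accepted <- records[ok, , drop = FALSE]
  accepted$sbp <- sbp[ok]; accepted$dbp <- dbp[ok]; accepted$pulse <- pulse[ok]
  rejected <- cbind(
    data.frame(row = which(!ok), reason = reason[!ok],
               stringsAsFactors = FALSE),
    records[!ok, , drop = FALSE]
  )
  rownames(accepted) <- rownames(rejected) <- NULL
  structure(list(accepted = accepted, rejected = rejected),
            class = "reading_validation")
}

#' @export
print.reading_validation <- function(x, ...) {
  cat(sprintf("Vital-sign validation: %d accepted, %d rejected\n",
              nrow(x$accepted), nrow(x$rejected)))
  if (nrow(x$rejected)) {
    tab <- table(x$rejected$reason)
    for (r in names(tab)) cat(sprintf("  %s: %d\n", r, tab[[r]]))
  }
  invisible(x)
}
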