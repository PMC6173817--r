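#' Traffic-light tier levels
#'
#' Tiers are ordered green < yellow < red. Helpers convert between the
#' character representation and the integer severity used internally.
#'
#' @keywords internal
#' @name tiers
NULL

TIER_LEVELS <- c("green", "yellow", "red")

tier_factor <- function(x) {
  factor(x, levels = TIER_LEVELS, ordered = TRUE)
}

tier_severity <- function(x) {
  match(as.character(x), TIER_LEVELS)
}

#' Default display-symbol map
#'
#' Maps an alerting condition to the display symbol shown on the device:
#' shock alerts use a flashing down arrow (higher urgency), hypertension-only
#' alerts a constant up arrow, and green readings show no symbol. Device
#' utility states (low battery, measurement error) are carried as entries so
#' a display layer can render them, but they play no part in classification.
#'
#' @return Named character vector mapping condition to symbol descriptor.
#' @export
#' @examples
#' default_display_map()
default_display_map <- function() {
  c(
    shock        = "flashing down arrow",
    hypertension = "constant up arrow",
    none         = "none",
    low_battery  = "battery symbol",
    error        = "error symbol"
  )
}

#' Traffic-light threshold configuration
#'
#' Builds the rule table that drives the early warning system: blood
#' pressure thresholds for the hypertension tiers and Shock Index (SI)
#' thresholds for the shock tiers. The defaults are the conventional
#' obstetric triggers: yellow at 140/90 mm Hg, red at 160/110 mm Hg,
#' SI yellow at 0.9 and SI red at 1.7.
#'
#' With `inclusive_boundaries = TRUE` (the default) a reading exactly at a
#' threshold triggers that tier (so 140/90 itself is yellow, matching the
#' usual "140/90 defines hypertension" convention); with `FALSE` the
#' comparisons are strict.
#'
#' @param hyp_yellow_sbp,hyp_yellow_dbp Yellow-tier blood pressure
#'   thresholds, mm Hg.
#' @param hyp_red_sbp,hyp_red_dbp Red-tier blood pressure thresholds, mm Hg.
#' @param si_yellow,si_red Shock Index thresholds (dimensionless).
#' @param inclusive_boundaries Logical; treat thresholds as inclusive
#'   (`>=`) rather than strict (`>`).
#' @param display_map Named character vector mapping conditions to display
#'   symbols; see [default_display_map()].
#' @return An object of class `vsa_thresholds`.
#' @export
#' @examples
#' cfg <- vsa_thresholds()
#' cfg
vsa_thresholds <- function(hyp_yellow_sbp = 140, hyp_yellow_dbp = 90,
                           hyp_red_sbp = 160, hyp_red_dbp = 110,
                           si_yellow = 0.9, si_red = 1.7,
                           inclusive_boundaries = TRUE,
                           display_map = default_display_map()) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop(sprintf("'%s' must be a single positive finite number", nm),
           call. = FALSE)
    as.numeric(x)
  }
  cfg <- list(
    hyp_yellow_sbp = num1(hyp_yellow_sbp, "hyp_yellow_sbp"),
    hyp_yellow_dbp = num1(hyp_yellow_dbp, "hyp_yellow_dbp"),
    hyp_red_sbp    = num1(hyp_red_sbp, "hyp_red_sbp"),
    hyp_red_dbp    = num1(hyp_red_dbp, "hyp_red_dbp"),
    si_yellow      = num1(si_yellow, "si_yellow"),
    si_red         = num1(si_red, "si_red"),
    inclusive_boundaries = isTRUE(inclusive_boundaries),
    display_map    = display_map
  )
  if (cfg$hyp_yellow_sbp >= cfg$hyp_red_sbp)
    stop("hyp_yellow_sbp must be below hyp_red_sbp", call. = FALSE)
  if (cfg$hyp_yellow_dbp >= cfg$hyp_red_dbp)
    stop("hyp_yellow_dbp must be below hyp_red_dbp", call. = FALSE)
  if (cfg$si_yellow >= cfg$si_red)
    stop("si_yellow must be below si_red", call. = FALSE)
  if (!is.character(display_map) || is.null(names(display_map)) ||
      !all(c("shock", "hypertension", "none") %in% names(display_map)))
    stop("display_map must name at least 'shock', 'hypertension' and 'none'",
         call. = FALSE)
  structure(cfg, class = "vsa_thresholds")
}

#' @export
print.vsa_thresholds <- function(x, ...) {
  cat("Traffic-light threshold configuration\n")
  cat(sprintf("  hypertension: yellow >= %g/%g, red >= %g/%g mm Hg\n",
              x$hyp_yellow_sbp, x$hyp_yellow_dbp,
              x$hyp_red_sbp, x$hyp_red_dbp))
  cat(sprintf("  shock index:  yellow >= %g, red >= %g\n",
              x$si_yellow, x$si_red))
  cat(sprintf("  boundaries:   %s\n",
              if (x$inclusive_boundaries) "inclusive (>=)" else "strict (>)"))
  invisible(x)
}

is_vsa_thresholds <- function(x) inherits(x, "vsa_thresholds")

assert_thresholds <- function(cfg) {
  if (!is_vsa_thresholds(cfg))
    stop("'cfg' must be a vsa_thresholds object; see vsa_thresholds()",
         call. = FALSE)
  invisible(cfg)
}
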