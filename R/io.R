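# Delimited-text readers/writers and threshold-config loading. All
# interchange is UTF-8 CSV with explicit headers and '.' decimal
# separator; no binary formats.

READINGS_COLUMNS <- c("subject_id", "timestamp", "sbp", "dbp", "pulse",
                      "context")

#' Read a vital-signs readings file
#'
#' Reads a CSV with header `subject_id,timestamp,sbp,dbp,pulse,context`
#' (extra columns are carried through), validates every row with
#' [validate_readings()], and reports rejected rows with their file line
#' numbers. Missing required columns are a hard error; bad rows are not.
#'
#' @param path Path to the readings CSV.
#' @return A `reading_validation` list (`accepted`, `rejected`); the
#'   `rejected` table's `line` column gives 1-based file line numbers
#'   (header = line 1).
#' @export
read_readings <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("subject_id", "sbp", "dbp", "pulse")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("readings file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  val <- validate_readings(raw)
  if (nrow(val$rejected))
    val$rejected$line <- val$rejected$row + 1L
  else
    val$rejected$line <- integer(0)
  val
}

#' Write alert results to CSV
#'
#' @param alerts Alert data frame from [vsa_alert()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alerts <- function(alerts, path) {
  utils::write.csv(alerts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a paired-study measurement file
#'
#' One measurement per row: `subject_id,position,source,sbp,dbp` with
#' optional `arm_circumference` and `cuff`.
#'
#' @param path Path to the CSV.
#' @return Measurement-sequence data frame for
#'   [build_comparison_pairs()].
#' @export
read_paired_study <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_sequence_table(x)
  x
}

#' Read an outcome-cohort file
#'
#' Reading columns as in [read_readings()] plus outcome columns; outcome
#' columns may be logical (`TRUE`/`FALSE`) or 0/1.
#'
#' @param path Path to the CSV.
#' @return Data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Load a traffic-light threshold configuration
#'
#' Reads a YAML file whose keys mirror [vsa_thresholds()] exactly
#' (`hyp_yellow_sbp`, `hyp_yellow_dbp`, `hyp_red_sbp`, `hyp_red_dbp`,
#' `si_yellow`, `si_red`, optional `inclusive_boundaries` and
#' `display_map`). Every missing required key is named in the error;
#' ordering violations (a yellow threshold at or above its red
#' counterpart) are rejected by the constructor. A commented template
#' ships at `system.file("extdata", "thresholds.yml", package =
#' "vsalert")`.
#'
#' @param path Path to the YAML configuration.
#' @return A [vsa_thresholds()] object.
#' @export
load_threshold_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  required <- c("hyp_yellow_sbp", "hyp_yellow_dbp", "hyp_red_sbp",
                "hyp_red_dbp", "si_yellow", "si_red")
  miss <- setdiff(required, names(cfg))
  if (length(miss))
    stop("threshold config missing required key(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  display <- if (is.null(cfg$display_map)) default_display_map()
    else unlist(cfg$display_map)
  out <- vsa_thresholds(
    hyp_yellow_sbp = cfg$hyp_yellow_sbp,
    hyp_yellow_dbp = cfg$hyp_yellow_dbp,
    hyp_red_sbp = cfg$hyp_red_sbp,
    hyp_red_dbp = cfg$hyp_red_dbp,
    si_yellow = cfg$si_yellow,
    si_red = cfg$si_red,
    inclusive_boundaries = if (is.null(cfg$inclusive_boundaries)) TRUE
      else isTRUE(cfg$inclusive_boundaries),
    display_map = display
  )
  if (is.null(cfg$display_map))
    message("display_map not given; using defaults")
  out
}

#' Write a run manifest
#'
#' Every CLI run emits one JSON manifest recording the command, inputs,
#' configuration digest, seed, package version, accepted/rejected row
#' counts and a timestamp, for field-audit traceability.
#'
#' @param path Output path for the manifest JSON.
#' @param command Subcommand name.
#' @param inputs Named list/character vector of input paths.
#' @param config Optional `vsa_thresholds` (digested into the manifest).
#' @param seed Optional integer seed.
#' @param accepted,rejected Row counts.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, command, inputs = list(), config = NULL,
                           seed = NULL, accepted = NA_integer_,
                           rejected = NA_integer_) {
  digest <- if (!is.null(config)) {
    flat <- unlist(config[setdiff(names(config), "display_map")])
    paste(names(flat), flat, sep = "=", collapse = ";")
  }
  manifest <- list(
    command = command,
    inputs = as.list(inputs),
    config_digest = digest,
    seed = seed,
    package_version = as.character(utils::packageVersion("vsalert")),
    rows_accepted = accepted,
    rows_rejected = rejected,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  invisible(manifest)
}
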