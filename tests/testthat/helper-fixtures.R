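# Shared fixtures: builders for readings, alternating measurement
# sequences and tier-outcome cohorts, plus canonical archetype readings
# per alert colour under the default thresholds.

default_cfg <- vsa_thresholds()

reading <- function(sbp, dbp, pulse, id = "s1") {
  data.frame(subject_id = id, sbp = sbp, dbp = dbp, pulse = pulse)
}

# archetype readings whose alert colour is the given tier (by either
# condition) under the default configuration
archetype <- list(
  green = c(sbp = 120, dbp = 70, pulse = 70),
  yellow = c(sbp = 145, dbp = 88, pulse = 70),
  red = c(sbp = 165, dbp = 112, pulse = 70)
)

cohort_of <- function(tiers, outcomes) {
  stopifnot(length(tiers) == length(outcomes))
  rows <- do.call(rbind, lapply(tiers, function(t) archetype[[t]]))
  out <- as.data.frame(rows)
  out$outcome <- outcomes
  out
}

# alternating same-arm sequence from explicit sbp values (dbp tracks
# sbp - 40 unless given); sources R,D,R,D,...
seq_of <- function(sbp, dbp = sbp - 40, id = "s1", arm = 28,
                   cuff = "medium") {
  m <- length(sbp)
  data.frame(subject_id = id, position = seq_len(m),
             source = rep(c("reference", "device"), length.out = m),
             sbp = sbp, dbp = dbp, arm_circumference = arm, cuff = cuff,
             stringsAsFactors = FALSE)
}

# pairs table straight from per-component difference vectors
pairs_of <- function(diff_sbp, diff_dbp = diff_sbp, arm = NULL) {
  n <- length(diff_sbp)
  p <- data.frame(subject_id = sprintf("s%d", seq_len(n)),
                  device_sbp = 120 + diff_sbp, device_dbp = 80 + diff_dbp,
                  reference_sbp = 120, reference_dbp = 80,
                  diff_sbp = diff_sbp, diff_dbp = diff_dbp,
                  stringsAsFactors = FALSE)
  if (!is.null(arm)) p$arm_circumference <- arm
  p
}
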