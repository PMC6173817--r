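# Seed-controlled generators for every input the analysis modules consume:
# mixed obstetric vital-sign populations, paired device-vs-reference
# studies with configurable bias structure, outcome cohorts with designed
# per-tier risks, and pre/post intervention indicator datasets.

# One master seed drives a deterministic seed tree so each sub-generator is
# independently reproducible. Streams are named; the derived seed depends
# only on (seed, stream) and stays inside 32-bit integer range.
derive_seed <- function(seed, stream) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed) ||
      seed != round(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  h <- sum(utf8ToInt(stream) * (seq_len(nchar(stream)) %% 31L + 1L))
  as.integer((abs(seed) %% 1000003L) * 2011L + h * 7919L) %% 2147483629L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Truncated-normal draws by rejection (vectorised, batched). Plausibility
# windows are wide relative to the class SDs, so acceptance is near 1.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (n == 0) return(numeric(0))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(max(n, 2L * (n - length(out))), mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Specification of a mixed obstetric vital-sign population
#'
#' Describes a three-class mixture — normotensive, hypertensive and
#' shocked (haemodynamic compromise from haemorrhage or sepsis) — with
#' per-class truncated-normal distributions for SBP, DBP and pulse and a
#' within-subject SBP–DBP correlation. The shocked-class defaults are
#' illustrative (low pressure, marked tachycardia); no published
#' population model fixes them.
#'
#' @param n Number of readings.
#' @param weights Mixture weights for (normotensive, hypertensive,
#'   shocked); must be non-negative and sum to 1.
#' @param classes Named list of per-class parameter lists, each with
#'   numeric `sbp`, `dbp`, `pulse` entries of the form `c(mean, sd)`.
#' @param sbp_dbp_cor Correlation between SBP and DBP within a subject,
#'   in (-1, 1).
#' @param seed Integer seed.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n,
                            weights = c(normotensive = 0.75,
                                        hypertensive = 0.20,
                                        shocked = 0.05),
                            classes = list(
                              normotensive = list(sbp = c(115, 10),
                                                  dbp = c(72, 8),
                                                  pulse = c(82, 10)),
                              hypertensive = list(sbp = c(155, 15),
                                                  dbp = c(100, 10),
                                                  pulse = c(85, 10)),
                              shocked = list(sbp = c(90, 12),
                                             dbp = c(55, 10),
                                             pulse = c(125, 15))),
                            sbp_dbp_cor = 0.7,
                            seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != round(n))
    stop("'n' must be a non-negative integer", call. = FALSE)
  if (length(weights) != 3L || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8)
    stop("'weights' must be 3 non-negative values summing to 1",
         call. = FALSE)
  if (is.null(names(weights)))
    names(weights) <- c("normotensive", "hypertensive", "shocked")
  if (!all(names(weights) %in% names(classes)))
    stop("'classes' must define every weighted class", call. = FALSE)
  if (abs(sbp_dbp_cor) >= 1)
    stop("'sbp_dbp_cor' must lie in (-1, 1)", call. = FALSE)
  for (nm in names(classes)) {
    cl <- classes[[nm]]
    for (f in c("sbp", "dbp", "pulse"))
      if (length(cl[[f]]) != 2L || cl[[f]][2] <= 0)
        stop(sprintf("class '%s' field '%s' must be c(mean, sd) with sd > 0",
                     nm, f), call. = FALSE)
    if (cl$dbp[1] >= cl$sbp[1])
      stop(sprintf("class '%s': mean DBP must be below mean SBP", nm),
           call. = FALSE)
  }
  structure(list(n = as.integer(n), weights = weights, classes = classes,
                 sbp_dbp_cor = sbp_dbp_cor, seed = as.integer(seed)),
            class = "population_spec")
}

# Draw one class's readings with correlated SBP/DBP and the sbp > dbp
# plausibility constraint enforced by rejection.
draw_class <- function(n, cl, rho) {
  if (n == 0)
    return(data.frame(sbp = numeric(0), dbp = numeric(0),
                      pulse = numeric(0)))
  sbp <- dbp <- pulse <- numeric(0)
  while (length(sbp) < n) {
    m <- 2L * (n - length(sbp)) + 8L
    z1 <- stats::rnorm(m); z2 <- stats::rnorm(m)
    # round to device resolution first, then enforce the windows so the
    # constraints hold on the values actually emitted
    s <- round(cl$sbp[1] + cl$sbp[2] * z1)
    d <- round(cl$dbp[1] + cl$dbp[2] * (rho * z1 + sqrt(1 - rho^2) * z2))
    p <- round(stats::rnorm(m, cl$pulse[1], cl$pulse[2]))
    ok <- s >= SBP_WINDOW[1] & s <= SBP_WINDOW[2] &
      d >= DBP_WINDOW[1] & d <= DBP_WINDOW[2] &
      p >= PULSE_WINDOW[1] & p <= PULSE_WINDOW[2] & s > d
    sbp <- c(sbp, s[ok]); dbp <- c(dbp, d[ok]); pulse <- c(pulse, p[ok])
  }
  data.frame(sbp = sbp[seq_len(n)], dbp = dbp[seq_len(n)],
             pulse = pulse[seq_len(n)])
}

#' Generate a mixed obstetric vital-sign population
#'
#' Draws readings from the mixture in a [population_spec()]. Pressures and
#' pulse are rounded to whole units (device resolution); every row passes
#' [validate_readings()]. The true class of each reading is kept in the
#' hidden-truth column `.class` for testing and calibration.
#'
#' @param spec A [population_spec()].
#' @return Data frame of readings: `subject_id`, `sbp`, `dbp`, `pulse`,
#'   `context`, `.class`.
#' @export
#' @examples
#' head(generate_population(population_spec(n = 5, seed = 7)))
generate_population <- function(spec) {
  if (!inherits(spec, "population_spec"))
    stop("'spec' must come from population_spec()", call. = FALSE)
  with_seed(derive_seed(spec$seed, "population"), {
    n <- spec$n
    if (n == 0)
      return(data.frame(subject_id = character(0), sbp = numeric(0),
                        dbp = numeric(0), pulse = numeric(0),
                        context = character(0), .class = character(0),
                        stringsAsFactors = FALSE))
    cls <- sample(names(spec$weights), n, replace = TRUE,
                  prob = spec$weights)
    out <- data.frame(sbp = numeric(n), dbp = numeric(n),
                      pulse = numeric(n), .class = cls,
                      stringsAsFactors = FALSE)
    for (nm in names(spec$weights)) {
      idx <- which(cls == nm)
      if (!length(idx)) next
      d <- draw_class(length(idx), spec$classes[[nm]], spec$sbp_dbp_cor)
      out$sbp[idx] <- d$sbp; out$dbp[idx] <- d$dbp
      out$pulse[idx] <- d$pulse
    }
    out$subject_id <- sprintf("P%04d", seq_len(n))
    out$context <- sample(READING_CONTEXTS[1:3], n, replace = TRUE,
                          prob = c(0.6, 0.15, 0.25))
    rownames(out) <- NULL
    out[, c("subject_id", "sbp", "dbp", "pulse", "context", ".class")]
  })
}

#' Specification of a paired device-vs-reference study
#'
#' Describes a validation study in which each subject contributes an
#' alternating same-arm measurement sequence (reference, device, ...,
#' reference; 7 measurements by default, giving 3 flanking-mean pairs).
#' Device values equal the subject's true pressure plus an
#' arm-circumference-dependent bias plus Gaussian error; reference values
#' get independent within-subject variability `ref_sd`. Bias and error may
#' be a single value applied to both pressures or a length-2
#' `c(sbp, dbp)` vector. The default bias structure emulates a cuff that
#' overestimates both pressures in large arms.
#'
#' @param n_subjects Number of subjects (default 52, 26 per arm band).
#' @param n_measurements Measurements per subject; odd values give the
#'   sequential alternating protocol, `2` gives a simultaneous one-pair
#'   (reference, device) design.
#' @param bias_small_arm,bias_large_arm Device bias (mm Hg) for arm
#'   circumference <= 32 cm and > 32 cm respectively.
#' @param error_sd Device measurement error SD, mm Hg.
#' @param ref_sd Within-subject reference variability SD, mm Hg.
#' @param arm_range Arm-circumference range, cm; subjects are split
#'   equally between the lower and upper halves (the 22–32 and 33–42 cm
#'   bands by default) and circumference drawn uniformly within the band.
#' @param cuff Cuff label recorded on every measurement.
#' @param seed Integer seed.
#' @return An object of class `paired_study_spec`.
#' @export
paired_study_spec <- function(n_subjects = 52, n_measurements = 7,
                              bias_small_arm = 1, bias_large_arm = 8,
                              error_sd = 4, ref_sd = 2,
                              arm_range = c(22, 42),
                              cuff = "wide_range", seed = 1L) {
  as2 <- function(x, nm) {
    if (!is.numeric(x) || !length(x) %in% c(1L, 2L))
      stop(sprintf("'%s' must be length 1 or 2 (sbp, dbp)", nm),
           call. = FALSE)
    if (length(x) == 1L) c(sbp = x, dbp = x) else c(sbp = x[1], dbp = x[2])
  }
  error_sd <- as2(error_sd, "error_sd")
  if (any(error_sd <= 0)) stop("'error_sd' must be > 0", call. = FALSE)
  if (any(as2(ref_sd, "ref_sd") < 0)) stop("'ref_sd' must be >= 0",
                                           call. = FALSE)
  if (n_measurements < 2) stop("need at least 2 measurements per subject",
                               call. = FALSE)
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_measurements = as.integer(n_measurements),
    bias_small_arm = as2(bias_small_arm, "bias_small_arm"),
    bias_large_arm = as2(bias_large_arm, "bias_large_arm"),
    error_sd = error_sd, ref_sd = as2(ref_sd, "ref_sd"),
    arm_range = arm_range, cuff = cuff, seed = as.integer(seed)
  ), class = "paired_study_spec")
}

#' Generate a paired device-vs-reference study
#'
#' Simulates the measurement-sequence table for a [paired_study_spec()]:
#' subjects' true pressures are drawn from a normotensive-to-hypertensive
#' range, then each sequence alternates reference and device measurements
#' with the configured bias and error structure.
#'
#' @param spec A [paired_study_spec()].
#' @return Data frame with one measurement per row (`subject_id`,
#'   `position`, `source`, `sbp`, `dbp`, `arm_circumference`, `cuff`),
#'   ready for [build_comparison_pairs()] / [run_validation()].
#' @export
#' @examples
#' seqs <- generate_paired_study(paired_study_spec(n_subjects = 4, seed = 3))
#' run_validation(seqs)
generate_paired_study <- function(spec) {
  if (!inherits(spec, "paired_study_spec"))
    stop("'spec' must come from paired_study_spec()", call. = FALSE)
  with_seed(derive_seed(spec$seed, "paired_study"), {
    ns <- spec$n_subjects
    if (ns == 0)
      return(data.frame(subject_id = character(0), position = integer(0),
                        source = character(0), sbp = numeric(0),
                        dbp = numeric(0), arm_circumference = numeric(0),
                        cuff = character(0), stringsAsFactors = FALSE))
    # two closed bands with a 1 cm gap at the midpoint, so every subject
    # sits unambiguously in the lower or upper arm-circumference stratum
    mid <- floor(mean(spec$arm_range))
    n_small <- ceiling(ns / 2)
    arm <- c(stats::runif(n_small, spec$arm_range[1], mid),
             stats::runif(ns - n_small, mid + 1, spec$arm_range[2]))
    true_sbp <- rtruncnorm(ns, 125, 18, 80, 220)
    true_dbp <- pmin(true_sbp - 15, rtruncnorm(ns, 78, 12, 40, 130))
    m <- spec$n_measurements
    rows <- lapply(seq_len(ns), function(i) {
      large <- arm[i] > mid
      bias <- if (large) spec$bias_large_arm else spec$bias_small_arm
      src <- rep(c("reference", "device"), length.out = m)
      is_dev <- src == "device"
      sbp <- ifelse(is_dev,
                    true_sbp[i] + bias["sbp"] +
                      stats::rnorm(m, 0, spec$error_sd["sbp"]),
                    true_sbp[i] + stats::rnorm(m, 0, spec$ref_sd["sbp"]))
      dbp <- ifelse(is_dev,
                    true_dbp[i] + bias["dbp"] +
                      stats::rnorm(m, 0, spec$error_sd["dbp"]),
                    true_dbp[i] + stats::rnorm(m, 0, spec$ref_sd["dbp"]))
      data.frame(subject_id = sprintf("S%03d", i), position = seq_len(m),
                 source = src, sbp = sbp, dbp = dbp,
                 arm_circumference = round(arm[i], 1), cuff = spec$cuff,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Specification of an outcome cohort with designed per-tier risks
#'
#' @param n Cohort size.
#' @param tier_proportions Designed proportions of (green, yellow, red)
#'   readings; non-negative, summing to 1.
#' @param tier_risks Designed adverse-outcome risks per tier.
#' @param outcome Name of the generated outcome column.
#' @param enforce_monotone Require `tier_risks` non-decreasing.
#' @param max_batches Bound on rejection-sampling batches per tier before
#'   the design is declared infeasible under the threshold configuration.
#' @param seed Integer seed.
#' @return An object of class `outcome_cohort_spec`.
#' @export
outcome_cohort_spec <- function(n,
                                tier_proportions = c(green = 0.70,
                                                     yellow = 0.20,
                                                     red = 0.10),
                                tier_risks = c(green = 0.02,
                                               yellow = 0.10,
                                               red = 0.30),
                                outcome = "adverse_outcome",
                                enforce_monotone = TRUE,
                                max_batches = 50L,
                                seed = 1L) {
  if (length(tier_proportions) != 3L || any(tier_proportions < 0) ||
      abs(sum(tier_proportions) - 1) > 1e-8)
    stop("'tier_proportions' must be 3 non-negative values summing to 1",
         call. = FALSE)
  if (length(tier_risks) != 3L || any(tier_risks < 0 | tier_risks > 1))
    stop("'tier_risks' must be 3 probabilities", call. = FALSE)
  names(tier_proportions) <- names(tier_risks) <- TIER_LEVELS
  if (enforce_monotone && any(diff(tier_risks) < 0))
    stop("'tier_risks' must be non-decreasing green -> yellow -> red",
         call. = FALSE)
  structure(list(n = as.integer(n), tier_proportions = tier_proportions,
                 tier_risks = tier_risks, outcome = outcome,
                 max_batches = as.integer(max_batches),
                 seed = as.integer(seed)),
            class = "outcome_cohort_spec")
}

# Per-tier proposal distributions for rejection sampling. Each targets one
# alert colour under typical threshold configurations; correctness does not
# depend on the targeting (draws are re-classified against cfg), only
# efficiency does.
tier_proposal <- function(tier, k) {
  draw <- function(k, ms, ss, md, sd_, mp, sp) {
    s <- stats::rnorm(k, ms, ss); d <- stats::rnorm(k, md, sd_)
    p <- stats::rnorm(k, mp, sp)
    data.frame(sbp = round(s), dbp = round(d), pulse = round(p))
  }
  half <- function(k) c(floor(k / 2), ceiling(k / 2))
  switch(tier,
    green = draw(k, 115, 10, 72, 8, 80, 9),
    yellow = {
      h <- half(k)
      rbind(draw(h[1], 148, 5, 95, 4, 85, 8),    # hypertensive yellow
            draw(h[2], 100, 8, 65, 7, 105, 8))   # shock yellow
    },
    red = {
      h <- half(k)
      rbind(draw(h[1], 172, 7, 115, 5, 88, 8),   # severe hypertension
            draw(h[2], 75, 6, 48, 6, 140, 10))   # profound shock
    })
}

#' Generate an outcome cohort with designed per-tier risks
#'
#' Draws vital-sign readings so that the cohort's alert colours under the
#' supplied threshold configuration match the designed tier proportions
#' (exact counts, largest-remainder rounding), by rejection sampling from
#' tier-targeted proposal distributions; every candidate is re-classified
#' against `cfg`, so correctness never depends on the proposals. Adverse
#' outcomes are Bernoulli draws at each tier's designed risk. The designed
#' tier is kept as hidden truth in `.design_tier`.
#'
#' @param spec An [outcome_cohort_spec()].
#' @param cfg A [vsa_thresholds()] configuration.
#' @return Data frame: `subject_id`, `sbp`, `dbp`, `pulse`, the outcome
#'   column named by the spec, and `.design_tier`.
#' @export
#' @examples
#' cohort <- generate_outcome_cohort(outcome_cohort_spec(n = 50, seed = 2))
#' table(vsa_alert(cohort)$colour)
generate_outcome_cohort <- function(spec, cfg = vsa_thresholds()) {
  if (!inherits(spec, "outcome_cohort_spec"))
    stop("'spec' must come from outcome_cohort_spec()", call. = FALSE)
  assert_thresholds(cfg)
  with_seed(derive_seed(spec$seed, "outcome_cohort"), {
    # largest-remainder apportionment of n across tiers
    raw <- spec$n * spec$tier_proportions
    counts <- floor(raw)
    rem <- spec$n - sum(counts)
    if (rem > 0) {
      top <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
      counts[top] <- counts[top] + 1
    }
    parts <- lapply(TIER_LEVELS, function(tier) {
      need <- counts[[tier]]
      if (need == 0)
        return(data.frame(sbp = numeric(0), dbp = numeric(0),
                          pulse = numeric(0)))
      got <- NULL
      for (batch in seq_len(spec$max_batches)) {
        cand <- tier_proposal(tier, max(4L * need, 64L))
        ok <- cand$sbp >= SBP_WINDOW[1] & cand$sbp <= SBP_WINDOW[2] &
          cand$dbp >= DBP_WINDOW[1] & cand$dbp <= DBP_WINDOW[2] &
          cand$pulse >= PULSE_WINDOW[1] & cand$pulse <= PULSE_WINDOW[2] &
          cand$sbp > cand$dbp
        cand <- cand[ok, , drop = FALSE]
        if (!nrow(cand)) next
        hit <- vsa_alert(cand, cfg)$colour == tier
        got <- rbind(got, cand[hit, , drop = FALSE])
        if (!is.null(got) && nrow(got) >= need) break
      }
      if (is.null(got) || nrow(got) < need)
        stop(sprintf(
          "could not realise tier '%s' under this configuration after %d batches; designed tier proportions appear infeasible",
          tier, spec$max_batches), call. = FALSE)
      got[seq_len(need), , drop = FALSE]
    })
    names(parts) <- TIER_LEVELS
    out <- do.call(rbind, lapply(TIER_LEVELS, function(tier) {
      d <- parts[[tier]]
      d$.design_tier <- rep(tier, nrow(d))
      d
    }))
    out$subject_id <- sprintf("C%05d", seq_len(nrow(out)))
    risk <- spec$tier_risks[out$.design_tier]
    out[[spec$outcome]] <- stats::runif(nrow(out)) < risk
    rownames(out) <- NULL
    out[, c("subject_id", "sbp", "dbp", "pulse", spec$outcome,
            ".design_tier")]
  })
}

#' Generate pre/post intervention indicator datasets
#'
#' Bernoulli draws of a binary per-woman indicator at the designed
#' proportion in each phase; reproducible given the seed.
#'
#' @param pre_p,post_p Designed indicator proportions per phase, in
#'   [0, 1].
#' @param n_pre,n_post Phase sizes.
#' @param seed Integer seed.
#' @return List with logical vectors `pre` and `post`.
#' @export
#' @examples
#' d <- generate_prepost(0.251, 0.169, 694, 547, seed = 11)
#' prepost_analysis(d$pre, d$post)$or$or
generate_prepost <- function(pre_p, post_p, n_pre, n_post, seed = 1L) {
  for (p in c(pre_p, post_p))
    if (!is.numeric(p) || p < 0 || p > 1)
      stop("proportions must lie in [0, 1]", call. = FALSE)
  if (n_pre < 0 || n_post < 0) stop("sizes must be non-negative",
                                    call. = FALSE)
  with_seed(derive_seed(seed, "prepost"), {
    list(pre = stats::runif(n_pre) < pre_p,
         post = stats::runif(n_post) < post_p)
  })
}
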