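test_that("shock index is the pulse/SBP ratio and rejects bad input", {
  expect_equal(shock_index(90, 100), 0.9)
  expect_equal(shock_index(100, 100), 1.0)
  expect_equal(shock_index(120, 80), 1.5)
  expect_equal(shock_index(c(90, 120), c(100, 80)), c(0.9, 1.5))
  expect_error(shock_index(90, 0), "positive")
  expect_error(shock_index(-5, 100), "positive")
  # display rounding is half-even and never feeds back into the ratio
  expect_equal(si_display(shock_index(101, 120)), 0.84)
  expect_equal(si_display(0.125), 0.12)
  expect_equal(si_display(0.135), 0.14)
})

test_that("hypertension tier follows the BP thresholds and ignores pulse", {
  cfg <- default_cfg
  tiers <- classify_hypertension(c(120, 145, 150), c(70, 88, 112), cfg)
  expect_equal(as.character(tiers), c("green", "yellow", "red"))
  # either component alone is enough
  expect_equal(as.character(classify_hypertension(138, 92, cfg)), "yellow")
  expect_equal(as.character(classify_hypertension(161, 70, cfg)), "red")
  # pulse-independence: same BP, any pulse, same tier via the full alert
  for (p in c(25, 60, 110, 240)) {
    a <- vsa_alert(reading(150, 95, p), cfg)
    expect_equal(as.character(a$hypertension_tier), "yellow")
  }
})

test_that("shock tier compares the exact ratio against the SI thresholds", {
  cfg <- default_cfg
  expect_equal(as.character(classify_shock(80, 120, cfg)), "green")
  expect_equal(as.character(classify_shock(108, 120, cfg)), "yellow")
  expect_equal(as.character(classify_shock(136, 80, cfg)), "red")
})

test_that("alert combines tiers with colour dominance and shock priority", {
  cfg <- default_cfg
  a <- vsa_alert(reading(162, 95, 70), cfg)  # SI 0.43, hypertension red
  expect_equal(as.character(a$colour), "red")
  expect_equal(as.character(a$condition), "hypertension")
  expect_equal(a$display, "constant up arrow")

  a <- vsa_alert(reading(100, 60, 95), cfg)  # SI 0.95, shock yellow
  expect_equal(as.character(a$colour), "yellow")
  expect_equal(as.character(a$condition), "shock")
  expect_equal(a$display, "flashing down arrow")

  a <- vsa_alert(reading(118, 75, 72), cfg)
  expect_equal(as.character(a$colour), "green")
  expect_equal(as.character(a$condition), "none")
  expect_equal(a$display, "none")

  # hypertension-red + shock-yellow: colour stays red, condition is shock,
  # and both component tiers are retained
  a <- vsa_alert(reading(165, 112, 150), cfg)  # SI 0.91
  expect_equal(as.character(a$colour), "red")
  expect_equal(as.character(a$shock_tier), "yellow")
  expect_equal(as.character(a$hypertension_tier), "red")
  expect_equal(as.character(a$condition), "shock")
  expect_equal(a$display, "flashing down arrow")
})

test_that("boundary readings trigger tiers only under inclusive mode", {
  inc <- vsa_thresholds(inclusive_boundaries = TRUE)
  str <- vsa_thresholds(inclusive_boundaries = FALSE)
  at <- list(  # reading exactly at each configured threshold
    list(r = reading(140, 70, 70), tier = "yellow", via = "hypertension"),
    list(r = reading(120, 90, 70), tier = "yellow", via = "hypertension"),
    list(r = reading(160, 70, 70), tier = "red", via = "hypertension"),
    list(r = reading(120, 110, 70), tier = "red", via = "hypertension"),
    list(r = reading(120, 70, 108), tier = "yellow", via = "shock"),
    list(r = reading(80, 41, 136), tier = "red", via = "shock")
  )
  for (case in at) {
    ai <- vsa_alert(case$r, inc)
    as_ <- vsa_alert(case$r, str)
    tier_i <- as.character(
      if (case$via == "shock") ai$shock_tier else ai$hypertension_tier)
    tier_s <- as.character(
      if (case$via == "shock") as_$shock_tier else as_$hypertension_tier)
    expect_equal(tier_i, case$tier)
    # under strict comparison the same reading sits just below the tier
    expect_lt(match(tier_s, c("green", "yellow", "red")),
              match(tier_i, c("green", "yellow", "red")))
  }
})

test_that("tier severities are monotone in the driving vital signs", {
  cfg <- default_cfg
  sev <- function(x) match(as.character(x), c("green", "yellow", "red"))
  set.seed(42)
  for (i in 1:200) {
    sbp <- sample(60:220, 1); dbp <- sample(30:min(sbp - 1, 140), 1)
    pulse <- sample(30:180, 1)
    base_h <- sev(classify_hypertension(sbp, dbp, cfg))
    base_s <- sev(classify_shock(pulse, sbp, cfg))
    # raising sbp or dbp never lowers the hypertension tier
    expect_gte(sev(classify_hypertension(min(sbp + 10, 300), dbp, cfg)),
               base_h)
    expect_gte(sev(classify_hypertension(sbp, min(dbp + 10, sbp - 1), cfg)),
               base_h)
    # raising pulse never lowers the shock tier
    expect_gte(sev(classify_shock(min(pulse + 15, 250), sbp, cfg)), base_s)
    # shock_index strictly monotone
    expect_gt(shock_index(pulse + 1, sbp), shock_index(pulse, sbp))
    expect_lt(shock_index(pulse, sbp + 1), shock_index(pulse, sbp))
  }
})

test_that("reading validation screens each invariant with a reason code", {
  v <- validate_readings(data.frame(sbp = 120, dbp = 80, pulse = 76))
  expect_equal(nrow(v$accepted), 1)
  expect_equal(nrow(v$rejected), 0)

  bad <- data.frame(
    sbp = c(80, 120, 120, 350, 120, NA),
    dbp = c(90, 80, 80, 80, 15, 80),
    pulse = c(76, 999, 76, 76, 76, 76))
  bad$pulse[3] <- 10
  v <- validate_readings(bad)
  expect_equal(nrow(v$accepted), 0)
  expect_equal(v$rejected$reason,
               c("sbp_not_above_dbp", "pulse_window", "pulse_window",
                 "sbp_window", "dbp_window", "missing_value"))
  expect_equal(v$rejected$row, 1:6)

  # mixed file: good rows survive, bad ones are reported, order preserved
  mix <- data.frame(sbp = c(120, 80, 110), dbp = c(80, 90, 70),
                    pulse = c(76, 76, 80))
  v <- validate_readings(mix)
  expect_equal(nrow(v$accepted), 2)
  expect_equal(v$rejected$row, 2)
  expect_error(validate_readings(data.frame(sbp = 1)), "required column")
})

test_that("threshold configuration enforces ordering and positivity", {
  expect_error(vsa_thresholds(hyp_yellow_sbp = 170), "below hyp_red_sbp")
  expect_error(vsa_thresholds(hyp_yellow_dbp = 115), "below hyp_red_dbp")
  expect_error(vsa_thresholds(si_yellow = 1.8), "below si_red")
  expect_error(vsa_thresholds(si_yellow = -1), "positive")
  expect_error(vsa_thresholds(display_map = c(a = "x")), "display_map")
})

test_that("alert agrees with a brute-force rule table on a random subgrid", {
  # independent recoding of the rule table; the exhaustive grid sweep
  # lives in the acceptance suite, this guards the property day to day
  oracle <- function(sbp, dbp, pulse) {
    hyp <- ifelse(sbp >= 160 | dbp >= 110, 3L,
                  ifelse(sbp >= 140 | dbp >= 90, 2L, 1L))
    shk <- ifelse(pulse / sbp >= 1.7, 3L,
                  ifelse(pulse / sbp >= 0.9, 2L, 1L))
    list(colour = pmax(hyp, shk),
         condition = ifelse(shk >= 2L, "shock",
                            ifelse(hyp >= 2L, "hypertension", "none")))
  }
  set.seed(99)
  sbp <- sample(60:220, 3000, replace = TRUE)
  dbp <- pmin(sample(30:140, 3000, replace = TRUE), sbp - 1)
  pulse <- sample(30:180, 3000, replace = TRUE)
  got <- vsa_alert(data.frame(sbp = sbp, dbp = dbp, pulse = pulse),
                   default_cfg)
  want <- oracle(sbp, dbp, pulse)
  expect_equal(match(as.character(got$colour), c("green", "yellow", "red")),
               want$colour)
  expect_equal(as.character(got$condition), want$condition)
})
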