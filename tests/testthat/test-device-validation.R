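test_that("pairing schemes follow the alternating-sequence protocol", {
  s <- seq_of(c(100, 102, 104, 106, 108, 110, 112))
  fm <- build_comparison_pairs(s, "flanking_mean")
  expect_equal(nrow(fm), 3)
  expect_equal(fm$diff_sbp, c(0, 0, 0))
  expect_equal(fm$reference_sbp, c(102, 106, 110))
  si <- build_comparison_pairs(s, "same_index")
  expect_equal(si$diff_sbp, c(2, 2, 2))

  # protocol violations
  expect_error(build_comparison_pairs(seq_of(rep(100, 6)), "flanking_mean"),
               "odd-length")
  bad <- seq_of(rep(100, 7)); bad$source[1] <- "device"
  expect_error(build_comparison_pairs(bad), "alternate")
  expect_error(build_comparison_pairs(seq_of(100), "same_index"),
               "at least one")

  # a simultaneous (reference, device) design maps onto same_index
  two <- seq_of(c(100, 103))
  expect_equal(build_comparison_pairs(two, "same_index")$diff_sbp, 3)

  # on a constant reference, flanking_mean and same_index coincide
  cst <- seq_of(c(110, 115, 110, 112, 110, 108, 110))
  expect_equal(build_comparison_pairs(cst, "flanking_mean")$diff_sbp,
               build_comparison_pairs(cst, "same_index")$diff_sbp)

  # covariates carried through
  s2 <- seq_of(rep(c(100, 104), length.out = 7), arm = 35, cuff = "large")
  p2 <- build_comparison_pairs(s2)
  expect_equal(unique(p2$arm_circumference), 35)
  expect_equal(unique(p2$cuff), "large")
})

test_that("difference statistics match hand values and a naive oracle", {
  expect_equal(unclass(difference_stats(pairs_of(c(0, 0, 0)))[
    c("mean_diff_sbp", "sd_diff_sbp")]),
    list(mean_diff_sbp = 0, sd_diff_sbp = 0))
  st <- difference_stats(pairs_of(c(2, 4, 6), c(1, 1, 1)))
  expect_equal(st$mean_diff_sbp, 4)
  expect_equal(st$sd_diff_sbp, 2)
  expect_equal(st$mean_diff_dbp, 1)

  # Monte-Carlo replication of a 255-pair comparison with designed bias
  # 2.2 and spread 6.1: the sample mean must land within 2 standard
  # errors (6.1/sqrt(255) = 0.382) of the design bias
  set.seed(255)
  d <- stats::rnorm(255, 2.2, 6.1)
  st <- difference_stats(pairs_of(d))
  expect_lt(abs(st$mean_diff_sbp - 2.2), 2 * 6.1 / sqrt(255))
  expect_equal(st$mean_diff_sbp, mean(d))
  expect_equal(st$sd_diff_sbp, sqrt(sum((d - mean(d))^2) / 254))

  # naive two-pass oracle agreement on random datasets
  set.seed(7)
  for (i in 1:50) {
    n <- sample(2:40, 1)
    ds <- stats::rnorm(n, stats::runif(1, -10, 10), stats::runif(1, 0.5, 9))
    dd <- stats::rnorm(n, 0, 3)
    st <- difference_stats(pairs_of(ds, dd))
    expect_equal(st$mean_diff_sbp, sum(ds) / n, tolerance = 1e-12)
    expect_equal(st$sd_diff_sbp,
                 sqrt(sum((ds - sum(ds) / n)^2) / (n - 1)),
                 tolerance = 1e-12)
    expect_equal(st$mean_diff_dbp, sum(dd) / n, tolerance = 1e-12)
  }

  # empty stratum is an explicit empty result, not zeros
  st <- difference_stats(pairs_of(c(1, 2)), stratum = c(FALSE, FALSE))
  expect_equal(st$n_pairs, 0)
  expect_true(is.na(st$mean_diff_sbp))
})

test_that("ISO assessment applies inclusive |mean| <= 5 and SD <= 8 bounds", {
  stat_of <- function(m, s) {
    # two-point set with exact mean m and SD s
    difference_stats(pairs_of(c(m - s / sqrt(2), m + s / sqrt(2))))
  }
  expect_true(iso_assess(stat_of(2.2, 6.1))$pass)
  expect_true(iso_assess(stat_of(5.0, 8.0))$pass)      # boundary inclusive
  expect_false(iso_assess(stat_of(5.1, 7.0))$sbp_pass) # mean bound
  expect_false(iso_assess(stat_of(0, 8.5))$pass)       # sd bound
  expect_true(iso_assess(stat_of(-4.9, 7.9))$pass)     # sign-symmetric
  # monotone: growing |mean| or SD never turns fail into pass
  set.seed(11)
  for (i in 1:50) {
    m <- stats::runif(1, 0, 8); s <- stats::runif(1, 0.5, 10)
    base <- iso_assess(stat_of(m, s))$sbp_pass
    worse <- iso_assess(stat_of(m + stats::runif(1, 0, 3),
                                s + stats::runif(1, 0, 3)))$sbp_pass
    if (!base) expect_false(worse)
  }
})

test_that("BHS grading awards the best grade whose criteria are all met", {
  expect_equal(bhs_grade(rep(0, 10)), "A")
  expect_equal(bhs_grade(rep(20, 10)), "D")
  # constructed 100-diff set hitting exactly the grade-B percentages:
  # 50 within 5, 75 within 10, 90 within 15 mm Hg
  d_b <- c(rep(0, 50), rep(8, 25), rep(13, 15), rep(20, 10))
  expect_equal(sum(abs(d_b) <= 5), 50)
  expect_equal(sum(abs(d_b) <= 10), 75)
  expect_equal(sum(abs(d_b) <= 15), 90)
  expect_equal(bhs_grade(d_b), "B")
  # grade-A and grade-C analogues by the same hand count
  d_a <- c(rep(0, 60), rep(8, 25), rep(13, 10), rep(20, 5))
  expect_equal(bhs_grade(d_a), "A")
  d_c <- c(rep(0, 40), rep(8, 25), rep(13, 20), rep(20, 15))
  expect_equal(bhs_grade(d_c), "C")
  # one band failing a grade drops the verdict even when the others pass:
  # 60/66/100 meets A's within-5 but only C's within-10 requirement
  d_fail10 <- c(rep(0, 60), rep(8, 6), rep(12, 34))
  expect_equal(bhs_grade(d_fail10), "C")
  # per-component grading from a pairs table
  g <- bhs_grade(pairs_of(rep(0, 10), rep(20, 10)))
  expect_equal(unname(g["sbp"]), "A")
  expect_equal(unname(g["dbp"]), "D")
  expect_error(bhs_grade(rep(0, 5), grade_table = data.frame(x = 1)),
               "grade table")
})

test_that("cumulative percentages are monotone and zero-diffs never hurt", {
  set.seed(21)
  for (i in 1:100) {
    d <- stats::rnorm(sample(1:60, 1), stats::runif(1, -8, 8),
                      stats::runif(1, 0.1, 12))
    cw <- cumulative_within(d)
    expect_true(cw["within_5"] <= cw["within_10"])
    expect_true(cw["within_10"] <= cw["within_15"])
    # appending a zero difference never lowers any cumulative percentage
    cw0 <- cumulative_within(c(d, 0))
    expect_true(all(cw0 >= cw - 1e-12))
    # ... never worsens the grade, and never grows |mean|
    grades <- c(A = 1, B = 2, C = 3, D = 4)
    expect_lte(grades[[bhs_grade(c(d, 0))]], grades[[bhs_grade(d)]])
    expect_lte(abs(mean(c(d, 0))), abs(mean(d)) + 1e-12)
  }
})

test_that("full validation pipeline reports overall and per-stratum", {
  # zero-difference study: perfect agreement, grades A/A, ISO pass
  seqs <- do.call(rbind, lapply(1:4, function(i)
    seq_of(rep(100 + 2 * i, 7), id = sprintf("s%d", i),
           arm = c(25, 28, 35, 40)[i])))
  rep0 <- run_validation(seqs)
  expect_true(rep0$iso$pass)
  expect_equal(unname(rep0$bhs), c("A", "A"))
  expect_equal(rep0$n_pairs, 12)
  expect_equal(rep0$strata$`22-32 cm`$n_pairs, 6)
  expect_equal(rep0$strata$`33-42 cm`$n_pairs, 6)

  # +15 mm Hg device bias confined to the large-arm stratum shows up in
  # that stratum's mean
  biased <- seqs
  dev <- biased$source == "device" & biased$arm_circumference >= 33
  biased$sbp[dev] <- biased$sbp[dev] + 15
  biased$dbp[dev] <- biased$dbp[dev] + 15
  repb <- run_validation(biased)
  expect_equal(repb$strata$`33-42 cm`$stats$mean_diff_sbp, 15)
  expect_equal(repb$strata$`22-32 cm`$stats$mean_diff_sbp, 0)
  expect_false(repb$strata$`33-42 cm`$iso$pass)
  expect_true(repb$strata$`22-32 cm`$iso$pass)
})

test_that("synthetic wide-range-cuff study fails ISO only in large arms", {
  seqs <- generate_paired_study(paired_study_spec(seed = 20))
  rep <- run_validation(seqs)
  expect_true(rep$strata$`22-32 cm`$iso$pass)
  expect_false(rep$strata$`33-42 cm`$iso$pass)
  expect_gt(rep$strata$`33-42 cm`$stats$mean_diff_sbp,
            rep$strata$`22-32 cm`$stats$mean_diff_sbp)
})
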