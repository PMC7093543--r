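# wear-time filtering, MET conversion, prevalence, per-type health summaries

test_that("wear-day validity uses inclusive 18 h / 20 h thresholds", {
  d <- data.frame(id = rep("a", 6),
                  day_type = c("weekday", "weekday", "weekday",
                               "weekend", "weekend", "weekend"),
                  wear_hours = c(18, 17.99, 24, 20, 19.5, 21))
  v <- filter_valid_wear_days(d)$records$valid
  expect_equal(v, c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE))
  expect_error(filter_valid_wear_days(transform(d, wear_hours = 25)),
               "\\[0, 24\\]")
})

test_that("eligibility needs 8 valid days with 4 weekdays and 1 weekend day", {
  mk <- function(id, wd, we) {
    data.frame(id = id,
               day_type = c(rep("weekday", wd), rep("weekend", we)),
               wear_hours = 23)
  }
  recs <- rbind(mk("mixed", 4, 4),      # 8 valid: 4 wd + 4 we -> eligible
                mk("allwd", 8, 0),      # 8 valid weekdays, no weekend -> not
                mk("short", 4, 3),      # only 7 valid days -> not
                mk("fewwd", 3, 5))      # 8 valid but 3 weekdays -> not
  el <- filter_valid_wear_days(recs)$eligible
  expect_true(el[["mixed"]])
  expect_false(el[["allwd"]])
  expect_false(el[["short"]])
  expect_false(el[["fewwd"]])
})

test_that("raising wear-time thresholds never enlarges the valid-day set", {
  set.seed(3)
  recs <- data.frame(id = rep(sprintf("p%d", 1:20), each = 10),
                     day_type = sample(c("weekday", "weekend"), 200, TRUE),
                     wear_hours = runif(200, 0, 24))
  base <- filter_valid_wear_days(recs)$records$valid
  for (bump in c(1, 3, 5)) {
    harder <- filter_valid_wear_days(recs, weekday_hours = 18 + bump,
                                     weekend_hours = 20 + bump)$records$valid
    expect_true(all(which(harder) %in% which(base)))
  }
})

test_that("MET converts to oxygen consumption linearly", {
  expect_equal(met_to_oxygen(1), 3.5)
  expect_equal(met_to_oxygen(0), 0)
  expect_equal(met_to_oxygen(2), 7.0)
  expect_error(met_to_oxygen(-0.1), "non-negative")
})

test_that("prevalence reproduces printed cohort percentages and its bounds", {
  expect_equal(prevalence(192, 4766), 4.0)
  expect_equal(prevalence(59, 5234), 1.1)
  expect_equal(prevalence(1089, 4766), 22.8)
  expect_equal(prevalence(0, 100), 0)
  expect_error(prevalence(5, 0), "positive")
  expect_error(prevalence(11, 10), "\\[0, total\\]")
  for (aff in c(0, 7, 53, 100)) {
    p <- prevalence(aff, 100)
    expect_true(p >= 0 && p <= 100)
    expect_equal(p + prevalence(100 - aff, 100), 100)
  }
})

test_that("per-participant activity summaries use valid days only", {
  act <- data.frame(id = "a",
                    day_type = c("weekday", "weekday"),
                    wear_hours = c(23, 2),
                    steps = c(9000, 0), met = c(1.5, 0.4))
  act <- rbind(act, data.frame(id = "a",
                               day_type = rep(c("weekday", "weekend"), c(6, 2)),
                               wear_hours = 23, steps = 9000, met = 1.5))
  participants <- data.frame(id = c("a", letters[2:11]), sex = "M",
                             age = c(50, 45 + 1:10))
  labels <- setNames(c("M1", rep("M2", 10)), participants$id)
  more <- do.call(rbind, lapply(letters[2:11], function(i)
    data.frame(id = i, day_type = rep(c("weekday", "weekend"), c(6, 2)),
               wear_hours = 23, steps = 5000, met = 1.2)))
  out <- activity_by_type(labels, participants, rbind(act, more))
  expect_equal(out$median_steps[out$label == "M1"], 9000)  # invalid day ignored
  expect_equal(out$median_met[out$label == "M2"], 1.2)
})

test_that("planted inactive obese archetype earns a negative tier-3 mark", {
  set.seed(10)
  n <- 200
  participants <- data.frame(id = sprintf("p%03d", 1:(2 * n)), sex = "M",
                             age = runif(2 * n, 55, 65))
  labels <- setNames(rep(c("M5", "M1"), each = n), participants$id)
  mets <- c(rnorm(n, 1.1, 0.1), rnorm(n, 1.6, 0.1))  # M5 clearly low
  act <- data.frame(id = rep(participants$id, each = 8),
                    day_type = rep(rep(c("weekday", "weekend"), c(6, 2)),
                                   2 * n),
                    wear_hours = 23,
                    steps = round(rep(mets, each = 8) * 6000),
                    met = rep(mets, each = 8))
  out <- activity_by_type(labels, participants, act)
  expect_equal(out$mark_met[out$label == "M5"], "---")
  expect_equal(out$mark_met[out$label == "M1"], "+++")
})

test_that("cross-type MET-BMI correlation behaves as planted", {
  expect_equal(cross_type_correlation(c(22, 25, 28, 31), c(1.8, 1.6, 1.4, 1.2)),
               -1)
  expect_warning(r <- cross_type_correlation(c(22, 25, 28), c(1.4, 1.4, 1.4)),
                 "constant")
  expect_true(is.na(r))
  expect_error(cross_type_correlation(c(22, 25), c(1, 2)), "3 types")
  # monotone in noise: correlation magnitude grows as noise shrinks
  set.seed(4)
  bmi <- seq(22, 32, length.out = 10)
  rs <- sapply(c(2, 0.5, 0.05), function(sg)
    cross_type_correlation(bmi, 2 - 0.05 * bmi + rnorm(10, 0, sg)))
  expect_true(all(diff(abs(rs)) > 0))
  expect_lt(rs[3], -0.95)
})

test_that("BMI-age slope across types matches two-point arithmetic and exclusions", {
  s <- data.frame(label = c("a", "b"), mean_age = c(45, 65),
                  mean_bmi = c(24, 29))
  expect_equal(bmi_age_slope(s), 0.25)
  flat <- data.frame(label = letters[1:4], mean_age = c(45, 50, 60, 65),
                     mean_bmi = 26)
  expect_equal(bmi_age_slope(flat), 0)
  # excluding a planted off-line outlier restores the planted slope
  online <- data.frame(label = letters[1:5],
                       mean_age = c(45, 50, 55, 60, 65),
                       mean_bmi = 24 + 0.25 * (c(45, 50, 55, 60, 65) - 45))
  outlier <- rbind(online, data.frame(label = "f", mean_age = 66,
                                      mean_bmi = 35))
  expect_false(isTRUE(all.equal(bmi_age_slope(outlier), 0.25)))
  expect_equal(bmi_age_slope(outlier, exclude = "f"), 0.25)
  expect_error(bmi_age_slope(s, exclude = c("a", "b")), "at least 2")
})

test_that("medication and lifestyle summaries aggregate consistently", {
  n <- 72
  ids <- sprintf("p%02d", 1:n)
  labels <- setNames(rep(c("F1", "F2", "M1"), each = n / 3), ids)
  health <- data.frame(id = ids,
                       pmi = FALSE,
                       smoking = rep(c("never", "former", "current"),
                                     length.out = n),
                       alcohol_g_day = rep(c(0, 10, 20), length.out = n),
                       atc_C = rep(c(TRUE, FALSE), length.out = n),
                       atc_G = FALSE, atc_H = FALSE)
  freq <- medication_frequency(labels, health, "C")
  expect_equal(unname(freq), rep(50, 3))
  expect_equal(unname(medication_frequency(labels, health, "G")), rep(0, 3))
  expect_error(medication_frequency(labels, health, "Z"), "unknown ATC")
  # per-type flag counts sum to the cohort count
  counts <- sapply(split(health$atc_C[match(names(labels), health$id)],
                         labels), sum)
  expect_equal(sum(counts), sum(health$atc_C))
  ls <- lifestyle_summary(labels, health)
  # 24 members per type, smoking cycling never/former/current: 16 smokers
  expect_equal(ls$pct_smokers, rep(prevalence(16, 24), 3))
  expect_equal(ls$pct_current, rep(prevalence(8, 24), 3))
  expect_equal(ls$mean_alcohol, rep(10, 3))
  # smokers subsume current and former: printed male example
  expect_equal(prevalence(1089 + 1715, 4766), 58.8)
  all_never <- transform(health, smoking = "never")
  expect_equal(lifestyle_summary(labels, all_never)$pct_smokers, rep(0, 3))
})
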