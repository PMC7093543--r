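# age correlations, bodygrams, incidence curves, smoothed trajectories

test_that("planted age trends are recovered with the analytically implied r", {
  cfg <- generator_config(n_male = 1000, n_female = 1000, seed = 12,
                          archetype_spec = NULL,
                          age_effect = c(A = 0, B = 0.4, C = -0.3, D = 0,
                                         E = 0, F = 0, G = 0, H = 0, I = 0,
                                         J = 0, K = 0, L = 0, M = 0),
                          age_effect_sex_mult = c(M = 1, F = 1))
  coh <- generate_cohort(cfg)
  p <- coh$participants
  z <- z_normalize(height_normalize(select_measures(coh$measures), p$height))
  def <- derive_metameasures(z, 13, method = "hclust")
  meta <- score_metameasures(z, def)
  r <- metameasure_age_correlation(meta, p$age, p$sex)
  # analytic r = slope * sd(age decades) / sd(meta score); the mixture-absorbed
  # factor model keeps total measure variance at 1, so
  # var(meta_b) = cross + resid_block + v_age + (1 - within)/n_b
  sd_u <- sqrt(40^2 / 12) / 10
  r_implied <- function(slope, n_b) {
    v_age <- slope^2 * sd_u^2
    slope * sd_u / sqrt(0.2 + max(0, 0.6 - v_age) + v_age + 0.2 / n_b)
  }
  n_b <- lengths(def$clusters)[c("B", "C")]
  for (s in c("F", "M")) {
    expect_lt(abs(r["B", s] - r_implied(0.4, n_b[["B"]])), 0.1)
    expect_lt(abs(r["C", s] - r_implied(-0.3, n_b[["C"]])), 0.1)
    expect_lt(r["C", s], 0)                     # decreasing thigh girth
    expect_lt(abs(r["H", s]), 0.1)              # age-independent axis near 0
  }
})

test_that("bodygrams are member means with exact linearity", {
  fx <- fixture_pipeline()
  whole <- bodygram(fx$meta)
  expect_lt(max(abs(whole)), 1e-9)     # whole-cohort bodygram is zero
  one <- bodygram(fx$meta, rownames(fx$meta)[5])
  expect_equal(one, fx$meta[5, ])      # single participant = its own row
  # linearity: union of disjoint groups = size-weighted mean
  g1 <- rownames(fx$meta)[1:100]; g2 <- rownames(fx$meta)[101:250]
  expect_equal(bodygram(fx$meta, c(g1, g2)),
               (100 * bodygram(fx$meta, g1) + 150 * bodygram(fx$meta, g2)) /
                 250)
  expect_error(bodygram(fx$meta, character(0)), "empty")
})

test_that("delta bodygrams flag pronounced changes and are antisymmetric", {
  fx <- fixture_pipeline()
  p <- fx$p
  young <- p$id[p$age >= 40 & p$age < 50]
  old <- p$id[p$age >= 70 & p$age <= 80]
  d <- delta_bodygram(fx$meta, young, old)
  expect_equal(unname(d), unname(-delta_bodygram(fx$meta, old, young)))
  expect_identical(attr(d, "flagged"), abs(d) > 0.2)
  # girth axes increase, upper-body lengths decrease with age (planted signs)
  expect_gt(d[["B"]], 0)
  expect_lt(d[["H"]], 0)
  expect_true(attr(d, "flagged")[["B"]])
  # identical strata give a zero, unflagged delta
  d0 <- delta_bodygram(fx$meta, young, young)
  expect_true(all(d0 == 0))
  expect_false(any(attr(d0, "flagged")))
})

test_that("incidence percentages are conserved and respond to planted age links", {
  fx <- fixture_pipeline()
  labels <- setNames(paste0(fx$p$archetype,
                            ifelse(fx$p$archetype %in% c("B1", "B2"),
                                   fx$p$sex, "")),
                     fx$p$id)
  inc <- incidence_by_age(labels, fx$p)
  for (s in c("F", "M")) {
    pct <- inc[[s]]
    occupied <- !apply(pct, 1, anyNA)
    expect_true(all(abs(rowSums(pct[occupied, , drop = FALSE]) - 100) < 1e-6))
  }
  # young-centred archetypes decline, old-centred ones rise (women)
  pctF <- inc$F
  occ <- which(!apply(pctF, 1, anyNA))
  expect_lt(pctF[occ[length(occ)], "F1"], pctF[occ[1], "F1"])
  expect_gt(pctF[occ[length(occ)], "F6"], pctF[occ[1], "F6"])
})

test_that("net incidence change follows the stated rule and sums to zero", {
  pct <- rbind(c(30, 10, 40, 20), c(20, 20, 40, 20))
  colnames(pct) <- c("A", "B", "C", "D")
  rownames(pct) <- c("[40,60)", "[60,80)")
  inc <- structure(list(F = pct, M = pct), class = "bt_incidence")
  nc <- net_incidence_change(inc)
  expect_equal(nc$F$net, 10)                       # A 30->20, B 10->20
  expect_equal(sum(nc$F$delta), 0, tolerance = 1e-6)
  expect_equal(net_incidence_change(inc, mode = "half_total_abs")$F$net, 10)
  flat <- structure(list(F = rbind(pct[1, , drop = FALSE],
                                   pct[1, , drop = FALSE]),
                         M = pct), class = "bt_incidence")
  rownames(flat$F) <- rownames(pct)
  expect_equal(net_incidence_change(flat)$F$net, 0)
  # net change in women exceeds men under the default generator (stronger
  # female aging slopes and age-linked female archetypes)
  fx <- fixture_pipeline()
  labels <- setNames(paste0(fx$p$archetype,
                            ifelse(fx$p$archetype %in% c("B1", "B2"),
                                   fx$p$sex, "")),
                     fx$p$id)
  nc2 <- net_incidence_change(incidence_by_age(labels, fx$p, bin_width = 10))
  expect_gt(nc2$F$net, nc2$M$net)
})

test_that("the loess smoother is exact on linear input and guards sample size", {
  ages <- seq(40, 75, length.out = 60)
  lin <- 20 + 0.1 * ages
  curve <- smoothed_index_curve(lin, ages)
  expect_equal(curve$value, 20 + 0.1 * curve$age, tolerance = 1e-6)
  const <- smoothed_index_curve(rep(25, 60), ages)
  expect_equal(const$value, rep(25, nrow(const)), tolerance = 1e-8)
  expect_error(smoothed_index_curve(lin[1:5], ages[1:5], type = "F9"), "F9")
  expect_error(smoothed_index_curve(rep(25, 30), rep(50:54, 6)),
               "2 decades")
})

test_that("per-type curves stay flat while the pooled mean rises (composition effect)", {
  # two planted types with constant but different BMI; the old-type share
  # grows with age, so the pooled curve rises although no type changes
  set.seed(8)
  n <- 600
  age <- runif(n, 40, 80)
  type <- ifelse(runif(n) < (age - 40) / 40, "old", "young")
  bmi <- ifelse(type == "old", 30, 24) + rnorm(n, 0, 0.3)
  young_curve <- smoothed_index_curve(bmi[type == "young"],
                                      age[type == "young"])
  old_curve <- smoothed_index_curve(bmi[type == "old"], age[type == "old"])
  pooled <- smoothed_index_curve(bmi, age)
  slope <- function(cv) coef(lm(value ~ age, cv))[2]
  expect_lt(abs(slope(young_curve)), 0.02)
  expect_lt(abs(slope(old_curve)), 0.02)
  expect_gt(slope(pooled), 0.08)
})
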