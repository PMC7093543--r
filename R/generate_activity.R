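#' Generate accelerometer day records for a cohort
#'
#' Simulates multi-day armband wear: each participant receives
#' `activity_days` day records (weekday/weekend pattern of a two-week
#' protocol) with wear hours, step counts and MET. Participant-level MET loads
#' negatively on BMI and age (configured loadings), steps track MET, and a
#' configurable fraction of days is generated with insufficient wear time to
#' exercise the validity filter. Per-sex marginal means and standard deviations
#' of steps and MET are calibrated at the participant level.
#'
#' @param cohort A `bt_cohort`.
#' @param cfg Generator configuration; defaults to the cohort's own.
#' @return Data frame with columns `id`, `day`, `day_type` (`"weekday"` /
#'   `"weekend"`), `wear_hours`, `steps`, `met`.
#' @export
generate_activity <- function(cohort, cfg = cohort$config) {
  validate_config(cfg)
  set.seed(cfg$seed + 1L)
  p <- cohort$participants
  if (!nrow(p)) {
    return(data.frame(id = character(0), day = integer(0),
                      day_type = character(0), wear_hours = numeric(0),
                      steps = numeric(0), met = numeric(0)))
  }
  bmi <- p$weight / (p$height / 100)^2

  met_i <- numeric(nrow(p)); steps_i <- numeric(nrow(p))
  for (sex in c("M", "F")) {
    i <- which(p$sex == sex)
    if (!length(i)) next
    a1 <- cfg$met_bmi_loading; a2 <- cfg$met_age_loading
    resid <- sqrt(max(0, 1 - a1^2 - a2^2))
    x <- a1 * as.numeric(scale(bmi[i])) + a2 * as.numeric(scale(p$age[i])) +
      resid * stats::rnorm(length(i))
    z_met <- as.numeric(scale(x))
    mm <- cfg$met[[sex]]
    met_i[i] <- pmax(0.3, mm[["mean"]] + mm[["sd"]] * z_met)
    cs <- cfg$steps_met_loading
    y <- cs * z_met + sqrt(1 - cs^2) * stats::rnorm(length(i))
    ss <- cfg$steps[[sex]]
    steps_i[i] <- lnorm_from_z(as.numeric(scale(y)), ss[["mean"]], ss[["sd"]])
  }

  nd <- cfg$activity_days
  day <- seq_len(nd)
  weekend <- ((day - 1L) %% 7L) >= 5L     # days 6,7 of each week
  n <- nrow(p)
  id <- rep(p$id, each = nd)
  day_type <- rep(ifelse(weekend, "weekend", "weekday"), n)
  is_we <- day_type == "weekend"
  ndr <- n * nd

  invalid <- stats::runif(ndr) < cfg$invalid_day_fraction
  wear <- numeric(ndr)
  wear[!invalid] <- ifelse(is_we[!invalid],
                           stats::runif(sum(!invalid), 20, 24),
                           stats::runif(sum(!invalid), 18, 24))
  wear[invalid] <- ifelse(is_we[invalid],
                          stats::runif(sum(invalid), 6, 19.5),
                          stats::runif(sum(invalid), 6, 17.5))

  met <- rep(met_i, each = nd) * lnorm_noise(ndr, cfg$met_day_cv)
  steps <- round(rep(steps_i, each = nd) * lnorm_noise(ndr, cfg$steps_day_cv))

  data.frame(id = id, day = rep(day, n), day_type = day_type,
             wear_hours = wear, steps = steps, met = met,
             stringsAsFactors = FALSE)
}

#' Generate health and lifestyle records for a cohort
#'
#' Draws per-participant self-reported previous myocardial infarction (PMI,
#' Bernoulli with sex-specific rate), smoking status (never/former/current),
#' zero-inflated alcohol consumption in g/day (point mass at zero plus an
#' exact-moment lognormal for drinkers, calibrated so the overall per-sex mean
#' and SD match the configuration), and medication flags for ATC groups C, G
#' and H.
#'
#' @inheritParams generate_activity
#' @return Data frame with columns `id`, `pmi` (logical), `smoking`
#'   (`"never"`, `"former"`, `"current"`), `alcohol_g_day`, `atc_C`, `atc_G`,
#'   `atc_H` (logical).
#' @export
generate_health <- function(cohort, cfg = cohort$config) {
  validate_config(cfg)
  set.seed(cfg$seed + 2L)
  p <- cohort$participants
  n <- nrow(p)
  out <- data.frame(id = p$id, pmi = logical(n),
                    smoking = character(n), alcohol_g_day = numeric(n),
                    atc_C = logical(n), atc_G = logical(n), atc_H = logical(n),
                    stringsAsFactors = FALSE)
  if (!n) return(out)
  for (sex in c("M", "F")) {
    i <- which(p$sex == sex)
    if (!length(i)) next
    out$pmi[i] <- stats::runif(length(i)) < cfg$pmi_rate[[sex]]
    sm <- cfg$smoking[[sex]]
    pr <- c(current = sm[["current"]], former = sm[["former"]],
            never = 1 - sm[["current"]] - sm[["former"]])
    if (pr[["never"]] < 0) stop("smoking rates for sex ", sex, " exceed 1")
    out$smoking[i] <- sample(names(pr), length(i), replace = TRUE, prob = pr)
    out$alcohol_g_day[i] <- draw_alcohol(length(i), cfg$alcohol[[sex]],
                                         cfg$alcohol_zero[[sex]])
    for (g in names(cfg$atc_rates))
      out[[paste0("atc_", g)]][i] <-
        stats::runif(length(i)) < cfg$atc_rates[[g]][[sex]]
  }
  out
}

# zero-inflated alcohol with exact overall moments
draw_alcohol <- function(n, marg, p0) {
  mu <- marg[["mean"]]; sg <- marg[["sd"]]
  mu_d <- mu / (1 - p0)
  var_d <- (sg^2 + mu^2) / (1 - p0) - mu_d^2
  if (var_d <= 0)
    stop("alcohol zero-inflation incompatible with configured mean/sd")
  x <- lnorm_from_z(stats::rnorm(n), mu_d, sqrt(var_d))
  x[stats::runif(n) < p0] <- 0
  x
}
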