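#' Wear-time validity filter for accelerometer days
#'
#' A day is valid if and only if it reaches at least 18 hours of wear on a
#' weekday or at least 20 hours on a weekend day (boundary values inclusive).
#' A participant is eligible if and only if they have at least 8 valid days,
#' among them at least 4 weekdays and at least 1 weekend day.
#'
#' @param records Data frame with columns `id`, `day_type` (`"weekday"` /
#'   `"weekend"`), `wear_hours`, and any further per-day columns.
#' @param weekday_hours,weekend_hours Wear-time thresholds in hours.
#' @param min_days,min_weekdays,min_weekend Eligibility thresholds.
#' @return List with `records` (input plus logical `valid` column),
#'   `eligible` (named logical per participant), and `valid_records` (the
#'   valid days of eligible participants only).
#' @export
#' @examples
#' d <- data.frame(id = "a", day_type = "weekday", wear_hours = 18)
#' filter_valid_wear_days(d)$records$valid  # TRUE: 18 h weekday is valid
filter_valid_wear_days <- function(records, weekday_hours = 18,
                                   weekend_hours = 20, min_days = 8L,
                                   min_weekdays = 4L, min_weekend = 1L) {
  stopifnot(all(c("id", "day_type", "wear_hours") %in% names(records)))
  if (any(records$wear_hours < 0 | records$wear_hours > 24))
    stop("wear_hours outside [0, 24]")
  if (!all(records$day_type %in% c("weekday", "weekend")))
    stop("day_type must be 'weekday' or 'weekend'")
  we <- records$day_type == "weekend"
  records$valid <- ifelse(we, records$wear_hours >= weekend_hours,
                          records$wear_hours >= weekday_hours)
  v <- records[records$valid, ]
  ids <- unique(records$id)
  n_valid <- table(factor(v$id, levels = ids))
  n_wd <- table(factor(v$id[v$day_type == "weekday"], levels = ids))
  n_we <- table(factor(v$id[v$day_type == "weekend"], levels = ids))
  eligible <- stats::setNames(as.vector(n_valid) >= min_days &
                                as.vector(n_wd) >= min_weekdays &
                                as.vector(n_we) >= min_weekend, ids)
  list(records = records, eligible = eligible,
       valid_records = v[eligible[v$id], ])
}

#' Convert MET to oxygen consumption
#'
#' One MET corresponds to the resting oxygen consumption of 3.5 ml O2 per kg
#' body weight per minute.
#'
#' @param met MET values (>= 0).
#' @return Oxygen consumption in ml O2 / kg / min.
#' @export
#' @examples
#' met_to_oxygen(1)  # 3.5
met_to_oxygen <- function(met) {
  if (any(met < 0)) stop("MET must be non-negative")
  met * 3.5
}

#' Prevalence percentage
#'
#' `100 * affected / total`, rounded half-up to one decimal (matching printed
#' cohort tables).
#'
#' @param affected Number of affected participants.
#' @param total Group size (> 0).
#' @return Percentage with one decimal.
#' @export
#' @examples
#' prevalence(192, 4766)  # 4.0
prevalence <- function(affected, total) {
  if (any(total <= 0)) stop("total must be positive")
  if (any(affected < 0 | affected > total))
    stop("affected must lie in [0, total]")
  round_half_up(100 * affected / total, 1)
}

#' Physical activity per body type
#'
#' Summarizes each body type's activity (median steps/day and median MET of
#' its eligible members, each member first averaged over their valid wear
#' days) and compares it against the type's age-matched, sex-specific
#' reference group by rank-sum test.
#'
#' @param labels Named body-type labels (sex-specific; mixed types split).
#' @param participants Data frame with `id`, `sex`, `age`.
#' @param activity Day records as produced by [generate_activity()].
#' @param window_years Reference-group age window.
#' @return Data frame per type: medians and significance marks for steps and
#'   MET (`NA` rows, with a warning, for types without eligible members).
#' @export
activity_by_type <- function(labels, participants, activity,
                             window_years = 10) {
  flt <- filter_valid_wear_days(activity)
  v <- flt$valid_records
  per <- stats::aggregate(v[, c("steps", "met")], by = list(id = v$id), mean)
  lab <- labels[per$id]
  per <- per[!is.na(lab), ]
  lab <- lab[!is.na(lab)]
  out <- lapply(sort(unique(labels)), function(tp) {
    ids <- names(labels)[labels == tp]
    i <- per$id %in% ids
    if (!any(i)) {
      warning("no eligible members in type ", tp)
      return(data.frame(label = tp, n = 0L, median_steps = NA_real_,
                        median_met = NA_real_, mark_steps = NA_character_,
                        mark_met = NA_character_, stringsAsFactors = FALSE))
    }
    ref_ids <- build_reference_group(ids, participants, window_years)
    j <- per$id %in% ref_ids
    ms <- compare_to_reference(per$steps[i], per$steps[j])
    mm <- compare_to_reference(per$met[i], per$met[j])
    data.frame(label = tp, n = sum(i),
               median_steps = stats::median(per$steps[i]),
               median_met = stats::median(per$met[i]),
               mark_steps = ms$mark, mark_met = mm$mark,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Cross-type correlation of mean MET with mean BMI
#'
#' Pearson correlation across body types of the types' mean MET against their
#' mean BMI; the expected association is strongly negative (less active, more
#' obese types).
#'
#' @param mean_bmi,mean_met Per-type means (aligned vectors, >= 3 types).
#' @return Pearson r (`NA` with a warning for degenerate input).
#' @export
cross_type_correlation <- function(mean_bmi, mean_met) {
  if (length(mean_bmi) < 3 || length(mean_met) != length(mean_bmi))
    stop("need aligned summaries of at least 3 types")
  if (stats::sd(mean_bmi) == 0 || stats::sd(mean_met) == 0) {
    warning("constant values across types; correlation undefined")
    return(NA_real_)
  }
  stats::cor(mean_bmi, mean_met)
}

#' Slope of per-type mean BMI on per-type mean age
#'
#' Ordinary least-squares slope (kg/m^2 per year) of the body types' mean BMI
#' on their mean age, with a configurable list of (typically obese, off-line)
#' types excluded.
#'
#' @param summaries Data frame with `label`, `mean_age`, `mean_bmi`.
#' @param exclude Type labels to drop before fitting.
#' @return Slope in kg/m^2 per year.
#' @export
#' @examples
#' s <- data.frame(label = c("a", "b"), mean_age = c(45, 65),
#'                 mean_bmi = c(24, 29))
#' bmi_age_slope(s)  # 0.25
bmi_age_slope <- function(summaries, exclude = character(0)) {
  s <- summaries[!summaries$label %in% exclude, ]
  if (nrow(s) < 2) stop("need at least 2 types after exclusions")
  unname(stats::coef(stats::lm(mean_bmi ~ mean_age, data = s))[2])
}

#' Medication frequency per body type
#'
#' Percentage of type members flagged for the given ATC medication group
#' (C: cardiovascular; G: genito-urinary and sex hormones; H: systemic
#' hormonal preparations excluding sex hormones and insulins), half-up rounded
#' to one decimal.
#'
#' @param labels Named body-type labels.
#' @param health Health records with columns `id`, `atc_C`, `atc_G`, `atc_H`.
#' @param atc_group `"C"`, `"G"` or `"H"`.
#' @return Named numeric vector of per-type percentages.
#' @export
medication_frequency <- function(labels, health, atc_group) {
  col <- paste0("atc_", atc_group)
  if (!col %in% names(health)) stop("unknown ATC group: ", atc_group)
  flag <- health[[col]][match(names(labels), health$id)]
  vapply(split(flag, labels), function(f)
    prevalence(sum(f), length(f)), numeric(1))
}

#' Lifestyle summary per body type
#'
#' Per-type smoker percentage (smokers subsume current and former smoking;
#' the current-only rate is reported alongside) and arithmetic mean alcohol
#' consumption in g/day.
#'
#' @param labels Named body-type labels.
#' @param health Health records with `id`, `smoking`, `alcohol_g_day`.
#' @return Data frame per type: `label`, `n`, `pct_smokers`, `pct_current`,
#'   `mean_alcohol`.
#' @export
lifestyle_summary <- function(labels, health) {
  h <- health[match(names(labels), health$id), ]
  out <- lapply(split(seq_along(labels), labels), function(i) {
    data.frame(
      n = length(i),
      pct_smokers = prevalence(sum(h$smoking[i] %in% c("current", "former")),
                               length(i)),
      pct_current = prevalence(sum(h$smoking[i] == "current"), length(i)),
      mean_alcohol = mean(h$alcohol_g_day[i])
    )
  })
  cbind(data.frame(label = names(out), stringsAsFactors = FALSE),
        do.call(rbind, out))
}
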