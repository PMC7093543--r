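#' Synthetic-cohort generator configuration
#'
#' Assembles the full configuration of the synthetic-cohort generator: sample
#' sizes, per-sex marginal distributions of the basic variables, the 13-block
#' correlation structure of the scanner measures, the 15-archetype body-shape
#' mixture, per-block aging slopes, activity and health-outcome parameters, and
#' the seed. Defaults emulate the study conditions of a middle-European adult
#' cohort aged 40--80: height 176 +/- 7 cm (men) and 165 +/- 7 cm (women),
#' weight 86 +/- 14 / 71 +/- 14 kg, waist 101 +/- 12 / 91 +/- 13 cm, steps per
#' day 9683 +/- 4011 / 9903 +/- 3682, MET 1.41 +/- 0.25 / 1.35 +/- 0.24,
#' alcohol 18.8 +/- 21.7 / 5.9 +/- 10.0 g/day, previous-myocardial-infarction
#' rates 4.0% / 1.1%, and smoking current/former rates 22.8%/36.0% (men) and
#' 19.4%/20.8% (women).
#'
#' @param n_male,n_female Participants per sex.
#' @param seed Integer seed governing all randomness of the generator.
#' @param age_range Recruitment age range in years (uniform sampling).
#' @param within_block_corr,cross_block_corr Target pairwise correlations of
#'   height-normalized measures inside one block and across blocks.
#' @param height_weight_corr Correlation between height and weight.
#' @param archetype_spec Data frame of body-shape archetypes as produced by
#'   [default_archetypes()], or `NULL` to disable the mixture (pure block
#'   covariance template).
#' @param age_effect Named numeric vector of per-block aging slopes in Z units
#'   per decade; positive for girth blocks, negative for upper-body lengths (H)
#'   and thigh girth (C).
#' @param age_effect_sex_mult Multipliers applied to `age_effect` per sex;
#'   the default makes female measures change more strongly with age.
#' @param registry Measure registry, see [measure_registry()].
#' @param invalid_day_fraction Fraction of generated accelerometer days that
#'   violate the wear-time validity rule.
#' @param activity_days Accelerometer days generated per participant.
#'
#' @return Object of class `bt_config` (a validated list).
#' @seealso [generate_cohort()], [plant_block_structure()]
#' @export
generator_config <- function(n_male = 500L, n_female = 500L, seed = 1L,
                             age_range = c(40, 80),
                             within_block_corr = 0.8, cross_block_corr = 0.2,
                             height_weight_corr = 0.5,
                             archetype_spec = default_archetypes(),
                             age_effect = default_age_effect(),
                             age_effect_sex_mult = c(M = 0.8, F = 1.2),
                             registry = measure_registry(),
                             invalid_day_fraction = 0.15,
                             activity_days = 14L) {
  cfg <- list(
    n_male = as.integer(n_male), n_female = as.integer(n_female),
    seed = as.integer(seed), age_range = age_range,
    height = list(M = c(mean = 176, sd = 7), F = c(mean = 165, sd = 7)),
    weight = list(M = c(mean = 86, sd = 14), F = c(mean = 71, sd = 14)),
    steps = list(M = c(mean = 9683, sd = 4011), F = c(mean = 9903, sd = 3682)),
    met = list(M = c(mean = 1.41, sd = 0.25), F = c(mean = 1.35, sd = 0.24)),
    alcohol = list(M = c(mean = 18.8, sd = 21.7), F = c(mean = 5.9, sd = 10.0)),
    alcohol_zero = c(M = 0.10, F = 0.30),
    height_weight_corr = height_weight_corr,
    weight_girth_loading = 0.8,
    within_block_corr = within_block_corr,
    cross_block_corr = cross_block_corr,
    registry = registry,
    archetype_spec = archetype_spec,
    archetype_age_width = 11,
    # normalized male-minus-female block shift in Z units (mirrors the
    # dimorphism encoded in the registry's raw-scale means); used for the
    # androgyny correction of mixed-sex archetypes
    sex_dimorphism = c(A = 0.6, B = 0.5, C = -0.8, D = 0.4, E = 0, F = -0.5,
                       G = -0.5, H = 0.6, I = 0.5, J = 0.3, K = 0.8, L = 0.5,
                       M = 0.6),
    androgyny = 1,
    age_effect = age_effect,
    age_effect_sex_mult = age_effect_sex_mult,
    station_waist_noise = 0.03,
    # activity model: MET latent loads negatively on BMI and age
    met_bmi_loading = -0.55, met_age_loading = -0.35,
    steps_met_loading = 0.8,
    met_day_cv = 0.06, steps_day_cv = 0.25,
    invalid_day_fraction = invalid_day_fraction,
    activity_days = as.integer(activity_days),
    pmi_rate = c(M = 0.040, F = 0.011),
    smoking = list(M = c(current = 0.228, former = 0.360),
                   F = c(current = 0.194, former = 0.208)),
    atc_rates = list(C = c(M = 0.32, F = 0.30),
                     G = c(M = 0.04, F = 0.18),
                     H = c(M = 0.06, F = 0.16))
  )
  class(cfg) <- "bt_config"
  validate_config(cfg)
  cfg
}

#' Default per-block aging slopes (Z units per decade)
#'
#' Girth blocks carry positive slopes, upper-body lengths (H) and thigh girth
#' (C) negative ones, so that on average all meta-measures except H and C rise
#' with age while the upper body shortens in relation to body size.
#'
#' @return Named numeric vector over blocks A--M.
#' @export
default_age_effect <- function() {
  c(A = 0.20, B = 0.35, C = -0.15, D = 0.10, E = 0.25, F = 0.05, G = 0.05,
    H = -0.35, I = 0.15, J = 0.20, K = 0.30, L = 0.30, M = 0.15)
}

#' Default body-shape archetype mixture
#'
#' Fifteen archetypes: six female (F1--F6), seven male (M1--M7) and two
#' mixed-sex (B1, B2). Each archetype is a mean-offset vector in meta-measure
#' space (Z units over blocks A--M) encoding a qualitative body-shape
#' description (e.g. "massive body, big girths" as large positive offsets on
#' the girth blocks B, C, K, L), a per-sex base mixing weight, and a central
#' recruitment age that shifts its incidence along the 40--80 y range. Offset
#' magnitudes are design parameters chosen so the archetypes are well separated
#' in meta-measure space; they are documented configuration, not estimates.
#'
#' @param separation Global multiplier applied to all offset vectors; the
#'   default keeps neighbouring archetypes roughly three within-type standard
#'   deviations apart in meta-measure space.
#' @return Data frame with columns `label`, `affinity` (`"F"`, `"M"` or
#'   `"B"`), `weight`, `age_center`, `age_width` (narrower for old-centred
#'   types: elderly body types collect a narrower age range), and one offset
#'   column per block A--M.
#' @export
default_archetypes <- function(separation = 1.15) {
  off <- function(...) {
    v <- stats::setNames(numeric(13), LETTERS[1:13])
    d <- c(...)
    v[names(d)] <- d
    v
  }
  rows <- list(
    # label    affinity weight age width offsets
    list("B1", "B", 0.08, 47, 12, off(B = -2.2, F =  1.8, G =  1.8, H =  1.2, C = -1.4, J =  1.0, D = -0.8)),
    list("B2", "B", 0.08, 62, 9, off(B =  1.8, A =  1.6, F = -1.6, G = -1.6, M =  1.2, K = 0.4, D =  0.8)),
    list("F1", "F", 0.14, 48, 12, off(B = -1.8, K = -1.4, L = -1.8, A = -1.2, C = -1.5)),
    list("F2", "F", 0.14, 56, 11, off(L = -2.0, I = -1.4, M =  2.0, H =  1.4)),
    list("F3", "F", 0.14, 58, 10, off(B =  1.2, C =  2.6, A =  1.2, L =  0.8)),
    list("F4", "F", 0.14, 60, 10, off(B =  3.2, C =  1.5, K =  2.2, L =  2.6, D = 0.6)),
    list("F5", "F", 0.14, 64, 9, off(H = -2.2, M = -1.8, J = -1.2)),
    list("F6", "F", 0.14, 67, 8, off(A =  1.8, E =  2.4, B =  1.0, J = -0.6)),
    list("M1", "M", 0.12, 49, 12, off(B = -1.5, I =  2.2, F =  1.5, G =  1.5, L = -1.6, K = -1.0)),
    list("M2", "M", 0.12, 55, 11, off(H =  2.4, M =  2.0, B = -0.6, J =  0.8)),
    list("M3", "M", 0.12, 57, 10, off(L =  2.2, K =  1.6, J =  0.8, I = 0.6)),
    list("M4", "M", 0.12, 59, 10, off(K =  2.6, F = -1.6, G = -1.6, J = -0.6, B = -0.6)),
    list("M5", "M", 0.12, 60, 10, off(B =  3.0, A =  1.5, K =  1.0, L =  1.8, H = 0.8)),
    list("M6", "M", 0.12, 61, 10, off(H =  1.5, M =  1.5, I = -2.2, G = -2.0, F = -1.0, E = -1.0)),
    list("M7", "M", 0.12, 66, 8, off(K =  1.8, C = -2.4, B =  0.6, E =  1.2))
  )
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(label = r[[1]], affinity = r[[2]], weight = r[[3]],
               age_center = r[[4]], age_width = r[[5]],
               t(r[[6]] * separation), stringsAsFactors = FALSE)
  }))
  rownames(out) <- out$label
  out
}

#' Validate a generator configuration
#'
#' Checks the invariants of the configuration: positive standard deviations,
#' per-sex mixing weights summing to one, disjoint block membership,
#' correlations strictly inside (-1, 1), and positive-definiteness of the
#' implied block covariance (which for the factor construction requires
#' `0 <= cross_block_corr <= within_block_corr < 1`).
#'
#' @param cfg A `bt_config` object.
#' @return `cfg`, invisibly; errors otherwise.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "bt_config"))
  if (cfg$n_male < 0 || cfg$n_female < 0)
    stop("participant counts must be non-negative")
  for (v in c("height", "weight", "steps", "met", "alcohol")) {
    sds <- vapply(cfg[[v]], function(x) x[["sd"]], numeric(1))
    if (any(sds <= 0)) stop("all configured standard deviations must be > 0 (", v, ")")
  }
  w <- cfg$within_block_corr; cr <- cfg$cross_block_corr
  if (w <= -1 || w >= 1 || cr <= -1 || cr >= 1)
    stop("correlations must lie in (-1, 1)")
  if (cr < 0 || cr > w)
    stop("implied covariance is not positive definite for block structure: ",
         "cross_block_corr must satisfy 0 <= cross <= within (block template)")
  if (abs(cfg$height_weight_corr) >= 1)
    stop("height_weight_corr must lie in (-1, 1)")
  if (cfg$height_weight_corr^2 + cfg$weight_girth_loading^2 > 1)
    stop("height_weight_corr and weight_girth_loading imply weight variance > 1")

  reg <- cfg$registry
  memb <- reg$name[reg$retained & reg$kind != "index"]
  if (anyDuplicated(memb))
    stop("duplicate measure in two blocks: ",
         paste(unique(memb[duplicated(memb)]), collapse = ", "))

  if (!is.null(cfg$archetype_spec)) {
    a <- cfg$archetype_spec
    for (s in c("M", "F")) {
      keep <- a$affinity %in% c(s, "B")
      tot <- sum(a$weight[keep])
      if (abs(tot - 1) > 1e-6)
        stop("archetype mixing weights for sex ", s, " must sum to 1 (got ",
             format(tot), ")")
    }
  }
  rates <- c(cfg$pmi_rate, unlist(cfg$atc_rates), cfg$alcohol_zero,
             unlist(cfg$smoking), cfg$invalid_day_fraction)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  invisible(cfg)
}

#' Correlation template implied by the block structure
#'
#' Expands the configured block specification into the full correlation matrix
#' of the (height-normalized) clustered scanner measures: `within_block_corr`
#' inside each of the 13 blocks, `cross_block_corr` across blocks, unity on
#' the diagonal.
#'
#' @param cfg A `bt_config` object.
#' @return Symmetric correlation matrix with measure names as dimnames and a
#'   `"blocks"` attribute giving each measure's block label.
#' @export
#' @examples
#' tpl <- plant_block_structure(generator_config())
#' length(unique(attr(tpl, "blocks")))  # 13
plant_block_structure <- function(cfg) {
  validate_config(cfg)
  reg <- cfg$registry
  keep <- reg$retained & reg$kind != "index"
  nm <- reg$name[keep]
  bl <- reg$block[keep]
  tpl <- matrix(cfg$cross_block_corr, length(nm), length(nm),
                dimnames = list(nm, nm))
  for (b in unique(bl)) {
    i <- which(bl == b)
    tpl[i, i] <- cfg$within_block_corr
  }
  diag(tpl) <- 1
  attr(tpl, "blocks") <- stats::setNames(bl, nm)
  tpl
}
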