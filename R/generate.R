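#' Generate a synthetic anthropometric cohort
#'
#' Draws a cohort with the statistical structure the downstream analysis
#' assumes: per-sex calibrated marginals for height, weight and waist; scanner
#' measures following a block-factor correlation model (13 blocks of correlated
#' measures), an additive body-shape archetype mixture and linear-in-age block
#' effects; and derived BMI/WHtR columns. All measures are generated directly
#' as numbers (no 3D mesh synthesis), and the raw length/girth scale is
#' proportional to body height so that the configured block correlations hold
#' exactly on the height-normalized scale.
#'
#' Marginal calibration is analytic: each measure's latent is standardized
#' against the theoretical moments of the archetype/age mixture and mapped
#' through an exact-moment lognormal (girths) or linear (lengths) transform, so
#' configured means and standard deviations are recovered up to sampling error
#' regardless of the planted structure.
#'
#' @param cfg A `bt_config` from [generator_config()].
#' @return Object of class `bt_cohort`: a list with `participants` (id, sex,
#'   age, height cm, weight kg, archetype label), `measures` (a raw
#'   [measure_matrix()] of 155 columns), and the generating `config`.
#'   Regenerating with the same configuration reproduces the cohort exactly.
#' @export
#' @examples
#' coh <- generate_cohort(generator_config(n_male = 50, n_female = 50, seed = 1))
#' dim(coh$measures)
generate_cohort <- function(cfg) {
  validate_config(cfg)
  set.seed(cfg$seed)
  reg <- cfg$registry

  parts <- list(); meas <- list()
  for (sex in c("M", "F")) {
    n <- if (sex == "M") cfg$n_male else cfg$n_female
    g <- generate_sex_stratum(cfg, sex, n)
    parts[[sex]] <- g$participants
    meas[[sex]] <- g$measures
  }
  participants <- rbind(parts$M, parts$F)
  measures <- rbind(meas$M, meas$F)
  if (nrow(participants)) {
    participants$id <- sprintf("P%05d", seq_len(nrow(participants)))
    rownames(measures) <- participants$id
    rownames(participants) <- NULL
    participants <- participants[, c("id", setdiff(names(participants), "id"))]
  }
  mm <- new_measure_matrix(measures, state = "raw", registry = reg)
  structure(list(participants = participants, measures = mm, config = cfg),
            class = "bt_cohort")
}

# draw one sex stratum; returns participants data frame + raw measure matrix
generate_sex_stratum <- function(cfg, sex, n) {
  reg <- cfg$registry
  blocks <- LETTERS[1:13]
  empty <- matrix(numeric(0), 0, nrow(reg), dimnames = list(NULL, reg$name))
  if (n == 0) {
    p <- data.frame(id = character(0), sex = character(0), age = numeric(0),
                    height = numeric(0), weight = numeric(0),
                    archetype = character(0), stringsAsFactors = FALSE)
    return(list(participants = p, measures = empty))
  }

  hw <- cfg$height[[sex]]; ww <- cfg$weight[[sex]]
  cv_h <- hw[["sd"]] / hw[["mean"]]
  age <- stats::runif(n, cfg$age_range[1], cfg$age_range[2])
  z_h <- stats::rnorm(n)
  height <- hw[["mean"]] + hw[["sd"]] * z_h

  # archetype assignment (age-kernel-weighted mixing)
  arch <- cfg$archetype_spec
  slopes <- cfg$age_effect * cfg$age_effect_sex_mult[[sex]]
  u <- (age - mean(cfg$age_range)) / 10   # age in decades from cohort center
  if (!is.null(arch)) {
    a <- arch[arch$affinity %in% c(sex, "B"), , drop = FALSE]
    pw <- archetype_age_probs(a, age, cfg$archetype_age_width)
    lab <- a$label[max.col(log(pw) + matrix(-log(stats::rexp(n * nrow(a))),
                                            n, nrow(a)))]  # Gumbel-max sampling
    eff <- effective_offsets(cfg, sex)
    offsets <- eff[match(lab, rownames(eff)), , drop = FALSE]
  } else {
    lab <- rep(NA_character_, n)
    offsets <- matrix(0, n, 13, dimnames = list(NULL, blocks))
  }

  mom <- mixture_block_moments(cfg, sex)

  # block latents: global + per-block factor + archetype offset + age effect.
  # The block-level variance contributed by the archetype mixture and the age
  # effect is absorbed into the within-block correlation budget, so the
  # planted within/cross correlations hold with and without the mixture.
  w <- cfg$within_block_corr; cr <- cfg$cross_block_corr
  lb <- sqrt(pmax((w - cr) - mom$v_extra, 0))   # residual block factor
  le <- sqrt(1 - w)
  G <- stats::rnorm(n)
  B <- matrix(stats::rnorm(n * 13), n, 13, dimnames = list(NULL, blocks))
  Tb <- sqrt(cr) * G + B * matrix(lb[blocks], n, 13, byrow = TRUE) + offsets +
    matrix(u, n, 13) * matrix(slopes, n, 13, byrow = TRUE)

  # scanner measures
  keep <- reg$retained & reg$kind != "index"
  out <- matrix(NA_real_, n, nrow(reg), dimnames = list(NULL, reg$name))
  for (j in which(keep)) {
    b <- reg$block[j]
    zeta <- (Tb[, b] + le * stats::rnorm(n) - mom$m1[b]) /
      sqrt(mom$var[b] + le^2)
    out[, j] <- measure_from_latent(zeta, reg[j, ], sex, height, hw, cv_h)
  }
  # non-retained auxiliary outputs share only the global factor
  for (j in which(!reg$retained)) {
    zeta <- sqrt(cr) * G + sqrt(1 - cr) * stats::rnorm(n)
    out[, j] <- measure_from_latent(zeta, reg[j, ], sex, height, hw, cv_h)
  }

  # weight: loads on height and on the upper-body-girth block latent so that
  # girthy archetypes are heavy; marginal calibrated exactly
  Ub <- (Tb[, "B"] - mom$m1["B"]) / sqrt(mom$var["B"])
  c_h <- cfg$height_weight_corr; c_u <- cfg$weight_girth_loading
  c_e <- sqrt(1 - c_h^2 - c_u^2)
  z_w <- c_h * z_h + c_u * Ub + c_e * stats::rnorm(n)
  weight <- lnorm_from_z(z_w, ww[["mean"]], ww[["sd"]])

  # derived index columns from station-style measurements
  waist_station <- out[, "waist_girth"] *
    exp(cfg$station_waist_noise * stats::rnorm(n) - cfg$station_waist_noise^2 / 2)
  out[, "bmi"] <- weight / (height / 100)^2
  out[, "whtr"] <- waist_station / height

  p <- data.frame(id = NA_character_, sex = sex, age = age, height = height,
                  weight = weight, archetype = lab, stringsAsFactors = FALSE)
  list(participants = p, measures = out)
}

# raw-scale transform of a standardized latent for one registry row
measure_from_latent <- function(zeta, row, sex, height, hw, cv_h) {
  mu <- if (sex == "M") row$mean_m else row$mean_f
  sg <- if (sex == "M") row$sd_m else row$sd_f
  if (!row$height_scaled) return(mu + sg * zeta)
  hr <- height / hw[["mean"]]
  if (row$kind == "length") {
    s_b2 <- sg^2 - (mu * cv_h)^2
    if (s_b2 <= 0) stop("length measure ", row$name,
                        " needs sd > mean * height CV")
    mu * hr + sqrt(s_b2) * zeta
  } else {
    s_b2 <- (sg^2 - mu^2 * cv_h^2) / (1 + cv_h^2)
    if (s_b2 <= 0) stop("girth measure ", row$name,
                        " needs sd > mean * height CV")
    hr * lnorm_from_z(zeta, mu, sqrt(s_b2))
  }
}

# age-conditional archetype probabilities (rows: participants); archetypes may
# carry their own kernel width (elderly types collect a narrower age range)
archetype_age_probs <- function(a, age, width) {
  w <- if (!is.null(a$age_width)) a$age_width else rep(width, nrow(a))
  pw <- vapply(seq_len(nrow(a)), function(j)
    stats::dnorm(age, a$age_center[j], w[j]) * a$weight[j],
    numeric(length(age)))
  pw <- matrix(pw, nrow = length(age))
  pw / rowSums(pw)
}

# realized male-minus-female dimorphism per block on the height-normalized
# scale, in units of the within-sex residual sd (the scale of the measure
# latents); computed from the registry marginals so the androgyny correction
# cancels exactly what the generated measures express
realized_block_dimorphism <- function(cfg) {
  reg <- cfg$registry
  reg <- reg[reg$retained & reg$kind != "index", ]
  hM <- cfg$height$M; hF <- cfg$height$F
  delta <- mapply(function(kind, hs, mM, sM, mF, sF) {
    norm_stats <- function(mu, sg, h) {
      cv_h <- h[["sd"]] / h[["mean"]]
      if (!hs) {                       # angles: divided by height downstream
        list(mean = mu / h[["mean"]],
             sd = sqrt(sg^2 + (mu * cv_h)^2) / h[["mean"]])
      } else if (kind == "length") {
        list(mean = mu / h[["mean"]],
             sd = sqrt(max(sg^2 - (mu * cv_h)^2, 1e-12)) / h[["mean"]])
      } else {                         # girths: lognormal base over height
        s_b2 <- (sg^2 - mu^2 * cv_h^2) / (1 + cv_h^2)
        list(mean = mu / h[["mean"]], sd = sqrt(max(s_b2, 1e-12)) / h[["mean"]])
      }
    }
    m <- norm_stats(mM, sM, hM)
    f <- norm_stats(mF, sF, hF)
    (m$mean - f$mean) / mean(c(m$sd, f$sd))
  }, reg$kind, reg$height_scaled, reg$mean_m, reg$sd_m, reg$mean_f, reg$sd_f)
  tapply(delta, reg$block, mean)[LETTERS[1:13]]
}

# per-sex archetype offsets with the androgyny correction for mixed types:
# members of B archetypes are pulled toward the sex midpoint of each block
# (females up / males down by half the realized normalized dimorphism)
effective_offsets <- function(cfg, sex) {
  blocks <- LETTERS[1:13]
  a <- cfg$archetype_spec[cfg$archetype_spec$affinity %in% c(sex, "B"), ,
                          drop = FALSE]
  eff <- as.matrix(a[, blocks])
  rownames(eff) <- a$label
  mixed <- a$affinity == "B"
  if (any(mixed)) {
    corr <- cfg$androgyny * realized_block_dimorphism(cfg) / 2 *
      (if (sex == "F") 1 else -1)
    eff[mixed, ] <- sweep(eff[mixed, , drop = FALSE], 2, corr, "+")
  }
  eff
}

# theoretical mean/variance of the (archetype offset + age effect) term per
# block, integrated over the age distribution on a fine grid; used to
# standardize measure latents so configured marginals are exact, and to size
# the residual block factor so the mixture variance counts toward the
# within-block correlation budget
mixture_block_moments <- function(cfg, sex) {
  blocks <- LETTERS[1:13]
  w <- cfg$within_block_corr; cr <- cfg$cross_block_corr
  slopes <- cfg$age_effect * cfg$age_effect_sex_mult[[sex]]
  grid <- seq(cfg$age_range[1], cfg$age_range[2], length.out = 161)
  u <- (grid - mean(cfg$age_range)) / 10
  arch <- cfg$archetype_spec
  if (is.null(arch)) {
    m1 <- stats::setNames(rep(0, 13), blocks)
    v_extra <- stats::setNames(slopes[blocks]^2 * mean(u^2), blocks)
  } else {
    a <- arch[arch$affinity %in% c(sex, "B"), , drop = FALSE]
    pw <- archetype_age_probs(a, grid, cfg$archetype_age_width)
    O <- effective_offsets(cfg, sex)[a$label, , drop = FALSE]
    m1 <- numeric(13); m2 <- numeric(13)
    for (b in seq_along(blocks)) {
      extra <- outer(u * slopes[blocks[b]], O[, b], `+`)   # grid x archetype
      m1[b] <- mean(rowSums(pw * extra))
      m2[b] <- mean(rowSums(pw * extra^2))
    }
    names(m1) <- blocks
    v_extra <- stats::setNames(m2 - m1^2, blocks)
  }
  list(m1 = m1, v_extra = v_extra,
       var = pmax(cr + v_extra, w))
}

#' Draw standardized measures from the pure block covariance template
#'
#' Samples the factor model that [plant_block_structure()] describes — within-
#' and cross-block correlations only, no archetype mixture, no age effects, no
#' sex dimorphism — and returns already height-normalized standardized values.
#' This is the reference input for structure-recovery checks of the
#' meta-measure derivation.
#'
#' @param cfg A `bt_config`.
#' @param n Number of participants to draw.
#' @param seed Integer seed.
#' @return A [measure_matrix()] (participants x 132 clustered measures) in
#'   state `"height_normalized"`.
#' @export
simulate_block_template <- function(cfg, n, seed = cfg$seed) {
  validate_config(cfg)
  set.seed(seed)
  tpl <- plant_block_structure(cfg)
  bl <- attr(tpl, "blocks")
  blocks <- unique(bl)
  w <- cfg$within_block_corr; cr <- cfg$cross_block_corr
  lg <- sqrt(cr); lb <- sqrt(w - cr); le <- sqrt(1 - w)
  G <- stats::rnorm(n)
  B <- matrix(stats::rnorm(n * length(blocks)), n, length(blocks),
              dimnames = list(NULL, blocks))
  out <- matrix(NA_real_, n, length(bl), dimnames = list(NULL, names(bl)))
  for (j in seq_along(bl))
    out[, j] <- lg * G + lb * B[, bl[j]] + le * stats::rnorm(n)
  rownames(out) <- sprintf("P%05d", seq_len(n))
  reg <- cfg$registry[match(names(bl), cfg$registry$name), ]
  new_measure_matrix(out, state = "height_normalized", registry = reg)
}

#' @export
print.bt_cohort <- function(x, ...) {
  cat("Synthetic anthropometric cohort:", nrow(x$participants),
      "participants (", sum(x$participants$sex == "M"), "male /",
      sum(x$participants$sex == "F"), "female ),",
      ncol(x$measures), "measures, seed", x$config$seed, "\n")
  invisible(x)
}
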