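#' Registry of synthetic scanner measures
#'
#' Builds the catalogue of body measures emitted by the synthetic-cohort
#' generator: 155 named columns of which 134 are flagged as retained for
#' analysis. The retained set comprises 132 scanner length/girth/angle measures
#' partitioned into the 13 meta-measure blocks A--M, plus the derived indices
#' BMI and WHtR (associated with the upper-body-girth block B), while 21
#' auxiliary scanner outputs (volumes, surface areas, symmetry scores) are kept
#' in the raw table but dropped from analysis.
#'
#' @details Each row describes one measure: its block label (`NA` for
#'   non-retained auxiliaries), its kind (`"length"`, `"girth"`, `"angle"`,
#'   `"index"`, `"misc"`), whether it is retained, whether its raw value scales
#'   with body height, and the per-sex marginal mean and standard deviation on
#'   the raw centimetre scale. Waist and hip girth carry literature-calibrated
#'   marginals (waist 101 +/- 12 cm men, 91 +/- 13 cm women; hip chosen so the
#'   mean waist-to-hip ratio is about 0.96 for men and 0.84 for women); the
#'   remaining defaults are plausible anthropometric scales whose exact values
#'   do not matter downstream because all analysis happens after
#'   height-normalization and Z-scoring.
#'
#' @return A data frame with one row per measure and columns `name`, `block`,
#'   `kind`, `retained`, `height_scaled`, `mean_m`, `sd_m`, `mean_f`, `sd_f`.
#' @export
#' @examples
#' reg <- measure_registry()
#' nrow(reg)                 # 155
#' sum(reg$retained)         # 134
#' table(reg$block[reg$retained & reg$kind != "index"])
measure_registry <- function() {
  blocks <- block_member_names()
  height_m <- 176; height_f <- 165

  # per-block raw-scale defaults: male base mean (cm or degrees), coefficient of
  # variation, kind, normalized male-minus-female dimorphism in Z units
  base <- list(
    A = list(mean = 40,  cv = 0.07, kind = "length", dimorph =  0.6),
    B = list(mean = 100, cv = 0.12, kind = "girth",  dimorph =  0.5),
    C = list(mean = 56,  cv = 0.10, kind = "girth",  dimorph = -0.8),
    D = list(mean = 57,  cv = 0.06, kind = "girth",  dimorph =  0.4),
    E = list(mean = 21,  cv = 0.16, kind = "angle",  dimorph =  0.0),
    F = list(mean = 109, cv = 0.06, kind = "length", dimorph = -0.5),
    G = list(mean = 82,  cv = 0.07, kind = "length", dimorph = -0.5),
    H = list(mean = 70,  cv = 0.07, kind = "length", dimorph =  0.6),
    I = list(mean = 62,  cv = 0.06, kind = "length", dimorph =  0.5),
    J = list(mean = 9,   cv = 0.15, kind = "length", dimorph =  0.3),
    K = list(mean = 39,  cv = 0.08, kind = "girth",  dimorph =  0.8),
    L = list(mean = 28,  cv = 0.11, kind = "girth",  dimorph =  0.5),
    M = list(mean = 46,  cv = 0.08, kind = "length", dimorph =  0.6)
  )

  rows <- lapply(names(blocks), function(b) {
    nm <- blocks[[b]]
    nb <- length(nm)
    spec <- base[[b]]
    # deterministic spread of member scales within a block
    mult <- seq(0.82, 1.22, length.out = nb)
    mean_m <- spec$mean * mult
    sd_m <- spec$cv * mean_m
    # dimorphism acts on the height-normalized scale: the male normalized mean
    # exceeds the female one by `dimorph` within-sex standard deviations
    mean_f <- mean_m * (height_f / height_m) / (1 + spec$dimorph * spec$cv)
    sd_f <- spec$cv * mean_f
    data.frame(
      name = nm, block = b, kind = spec$kind, retained = TRUE,
      height_scaled = spec$kind != "angle",
      mean_m = mean_m, sd_m = sd_m, mean_f = mean_f, sd_f = sd_f,
      stringsAsFactors = FALSE
    )
  })
  reg <- do.call(rbind, rows)

  # literature-calibrated marginals for the index-bearing girths
  reg[reg$name == "waist_girth", c("mean_m", "sd_m", "mean_f", "sd_f")] <-
    list(101, 12, 91, 13)
  reg[reg$name == "hip_girth", c("mean_m", "sd_m", "mean_f", "sd_f")] <-
    list(105, 9, 108, 10)

  idx <- data.frame(
    name = c("bmi", "whtr"), block = "B", kind = "index", retained = TRUE,
    height_scaled = FALSE,
    mean_m = NA_real_, sd_m = NA_real_, mean_f = NA_real_, sd_f = NA_real_,
    stringsAsFactors = FALSE
  )

  aux <- data.frame(
    name = dropped_measure_names(), block = NA_character_, kind = "misc",
    retained = FALSE, height_scaled = TRUE,
    mean_m = 50 * seq(0.6, 1.6, length.out = 21),
    sd_m = NA_real_, mean_f = NA_real_, sd_f = NA_real_,
    stringsAsFactors = FALSE
  )
  aux$sd_m <- 0.15 * aux$mean_m
  aux$mean_f <- aux$mean_m * (height_f / height_m)
  aux$sd_f <- 0.15 * aux$mean_f

  out <- rbind(reg, idx, aux)
  rownames(out) <- NULL
  stopifnot(nrow(out) == 155L, sum(out$retained) == 134L)
  out
}

#' Meta-measure block membership of the synthetic scanner measures
#'
#' The 13 blocks A--M of correlated measures: shoulder width (A), upper-body
#' girths (B), thigh girth (C), head circumference (D), shoulder angle (E),
#' sideseam length (F), inseam length (G), upper-body lengths (H), arm length
#' (I), neck length (J), neck girth (K), arm girth (L), and torso length (M).
#'
#' @return Named list mapping block label to member measure names (scanner
#'   measures only; the derived indices BMI and WHtR are associated with block B
#'   in [measure_registry()] but are not generated as scanner outputs).
#' @export
block_member_names <- function() {
  lr <- function(x) paste0(x, c("_left", "_right"))
  list(
    A = c("shoulder_width", "armpit_width", "cross_shoulder_length",
          "shoulder_breadth_back", "shoulder_breadth_front", "acromion_width",
          "biacromial_length", "shoulder_arc_length"),
    B = c("chest_girth", "waist_girth", "hip_girth", "belly_circumference",
          "bust_girth", "underbust_girth", "high_hip_girth",
          "max_belly_circumference", "waist_band_girth", "seat_girth",
          "abdomen_girth", "torso_girth", "chest_girth_scye",
          "waist_girth_preferred", "hip_girth_maximum", "buttock_girth",
          "upper_chest_girth", "lower_waist_girth"),
    C = c(lr("thigh_girth"), lr("mid_thigh_girth"), lr("knee_girth")),
    D = c("head_circumference", "crotch_length", "head_breadth", "head_length",
          "face_height", "crotch_length_front"),
    E = c(lr("shoulder_angle"), lr("shoulder_slope")),
    F = c(lr("sideseam_length"), lr("ankle_height_sideseam"), "head_height",
          "waist_height", "hip_height", lr("knee_height"),
          lr("outside_leg_length"), "iliac_spine_height", "trochanter_height",
          "tibiale_height"),
    G = c(lr("inseam_length"), lr("ankle_height_inseam"), "crotch_height",
          lr("inside_leg_length"), lr("crotch_height_side"),
          lr("gluteal_fold_height"), lr("calf_height"), "mid_patella_height"),
    H = c("neck_to_hip_distance", "neck_to_knee_distance",
          "waist_to_knee_distance", "neck_to_buttock_length",
          "cervicale_to_hip_length", "cervicale_to_knee_length",
          "back_length_to_hip", "front_length_to_hip",
          lr("side_upper_body_length"), "trunk_length_back",
          "trunk_length_front"),
    I = c(lr("arm_length"), lr("up_arm_length"), lr("forearm_length"),
          lr("shoulder_to_wrist"), lr("shoulder_to_elbow")),
    J = c("neck_length", "neck_length_front", "neck_length_back",
          "neck_height"),
    K = c("neck_girth_base", "neck_girth_middle", "neck_girth_upper",
          "neck_base_arc_length", "neck_girth_relaxed", "neck_girth_flexed"),
    L = c(lr("forearm_girth"), lr("up_arm_girth"), lr("elbow_girth"),
          lr("ankle_girth"), lr("wrist_girth"), lr("biceps_girth_flexed"),
          lr("max_forearm_girth"), lr("calf_girth"), lr("min_ankle_girth")),
    M = c("neck_to_waist_left", "neck_to_waist_right", "neck_to_waist_central",
          "back_neck_to_waist", "front_neck_to_waist",
          lr("side_neck_to_waist"), "cervicale_to_waist", "sternum_to_waist",
          "scye_depth", "chest_to_waist_length", "front_torso_arc")
  )
}

# the 21 scanner outputs emitted but not retained for analysis
dropped_measure_names <- function() {
  c("body_surface_area", "body_volume", "torso_volume", "leg_volume_left",
    "leg_volume_right", "arm_volume_left", "arm_volume_right",
    "left_right_leg_symmetry", "left_right_arm_symmetry", "posture_angle",
    "torso_twist_angle", "pelvis_tilt_angle", "scan_height_check",
    "mesh_quality_score", "arm_axilla_area_left", "arm_axilla_area_right",
    "hand_span_left", "hand_span_right", "foot_length_left",
    "foot_length_right", "chin_height")
}

#' Default retained-measure names
#'
#' @param registry Optional registry data frame from [measure_registry()].
#' @return Character vector of the 134 retained measure names.
#' @export
retained_measure_names <- function(registry = measure_registry()) {
  registry$name[registry$retained]
}
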