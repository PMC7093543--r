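#' Classical body indices
#'
#' Computes BMI, waist-to-hip ratio (WTH), waist-to-height ratio (WHtR) and
#' "a body shape index" (ABSI) from weight and the three basic dimensions.
#' Formulas: BMI = weight / height^2 (kg/m^2); WTH = waist / hip;
#' WHtR = waist / height; ABSI = waist / (BMI^(2/3) * height^(1/2)) with waist
#' and height in metres, giving units of m^(11/6) kg^(-2/3).
#'
#' @param weight_kg Body weight in kilograms.
#' @param height_m Body height in metres.
#' @param waist_m Waist circumference in metres.
#' @param hip_m Hip circumference in metres.
#' @return Data frame with columns `bmi`, `wth`, `whtr`, `absi`,
#'   `bmi_category`.
#' @export
#' @examples
#' compute_body_indices(86, 1.76, 1.01, 1.05)$bmi  # 27.76
compute_body_indices <- function(weight_kg, height_m, waist_m, hip_m) {
  args <- list(weight_kg = weight_kg, height_m = height_m,
               waist_m = waist_m, hip_m = hip_m)
  for (nm in names(args))
    if (any(!is.finite(args[[nm]]) | args[[nm]] <= 0))
      stop("non-positive or non-finite value in ", nm)
  bmi <- weight_kg / height_m^2
  data.frame(
    bmi = bmi,
    wth = waist_m / hip_m,
    whtr = waist_m / height_m,
    absi = waist_m / (bmi^(2 / 3) * sqrt(height_m)),
    bmi_category = bmi_category(bmi),
    stringsAsFactors = FALSE
  )
}

#' WHO BMI category
#'
#' Half-open boundaries: underweight (BMI < 18.5), normal
#' (18.5 <= BMI < 25), overweight (25 <= BMI < 30), obese (BMI >= 30).
#'
#' @param bmi Numeric BMI values (kg/m^2), positive and finite.
#' @return Factor with levels `underweight`, `normal`, `overweight`, `obese`.
#' @export
#' @examples
#' bmi_category(c(24.99, 25, 30))  # normal, overweight, obese
bmi_category <- function(bmi) {
  if (any(!is.finite(bmi) | bmi <= 0)) stop("BMI must be finite and positive")
  cut(bmi, breaks = c(0, 18.5, 25, 30, Inf), right = FALSE,
      labels = c("underweight", "normal", "overweight", "obese"))
}

#' Body indices for every cohort participant
#'
#' Convenience wrapper extracting weight, height, waist girth and hip girth
#' from a cohort (cm converted to metres) and applying
#' [compute_body_indices()].
#'
#' @param cohort A `bt_cohort`.
#' @return Data frame with `id` plus the index columns.
#' @export
cohort_body_indices <- function(cohort) {
  p <- cohort$participants
  m <- cohort$measures
  if (measure_state(m) != "raw")
    stop("cohort measures must be on the raw (cm) scale")
  cbind(data.frame(id = p$id, stringsAsFactors = FALSE),
        compute_body_indices(p$weight, p$height / 100,
                             unclass(m)[, "waist_girth"] / 100,
                             unclass(m)[, "hip_girth"] / 100))
}
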