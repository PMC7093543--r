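#' Measure matrices with an explicit normalization state
#'
#' A `bt_measures` object is a numeric participants-by-measures matrix carrying
#' a normalization state (`"raw"`, `"height_normalized"` or `"z_scored"`) and
#' per-column metadata (block label, measure kind, retained flag). The state
#' machine is strict: Z-scoring is only permitted on height-normalized input,
#' so no processing step can be skipped silently.
#'
#' @param x Numeric matrix with participant rownames and measure colnames.
#' @param state Normalization state flag.
#' @param registry Data frame with at least `name`, `block`, `kind`,
#'   `retained`, `height_scaled` covering the columns of `x`.
#' @return A `bt_measures` matrix.
#' @export
new_measure_matrix <- function(x, state = c("raw", "height_normalized",
                                            "z_scored"),
                               registry) {
  state <- match.arg(state)
  stopifnot(is.matrix(x), is.numeric(x))
  reg <- registry[match(colnames(x), registry$name), , drop = FALSE]
  if (anyNA(reg$name))
    stop("registry does not cover columns: ",
         paste(setdiff(colnames(x), registry$name), collapse = ", "))
  structure(x, state = state, registry = reg, class = c("bt_measures", "matrix",
                                                        "array"))
}

#' Normalization state of a measure matrix
#' @param x A `bt_measures` object.
#' @return One of `"raw"`, `"height_normalized"`, `"z_scored"`.
#' @export
measure_state <- function(x) attr(x, "state")

#' Column metadata of a measure matrix
#' @param x A `bt_measures` object.
#' @return The registry rows describing the columns of `x`.
#' @export
measure_info <- function(x) attr(x, "registry")

#' @export
print.bt_measures <- function(x, ...) {
  cat("<bt_measures> ", nrow(x), " participants x ", ncol(x), " measures, state: ",
      measure_state(x), "\n", sep = "")
  invisible(x)
}

#' Restrict a measure matrix to the retained measure set
#'
#' @param x A `bt_measures` matrix (any state).
#' @param retained Character vector of measure names to keep; defaults to the
#'   registry's retained flag (134 of 155 by default). Column order of `x` is
#'   preserved.
#' @return A `bt_measures` matrix with the retained columns only.
#' @export
#' @examples
#' coh <- generate_cohort(generator_config(n_male = 5, n_female = 5))
#' ncol(select_measures(coh$measures))  # 134
select_measures <- function(x, retained = NULL) {
  stopifnot(inherits(x, "bt_measures"))
  reg <- measure_info(x)
  if (is.null(retained)) retained <- reg$name[reg$retained]
  missing <- setdiff(retained, colnames(x))
  if (length(missing))
    stop("retained measures absent from matrix: ",
         paste(missing, collapse = ", "))
  keep <- colnames(x)[colnames(x) %in% retained]
  new_measure_matrix(unclass(x)[, keep, drop = FALSE],
                     state = measure_state(x), registry = reg)
}

#' Height-normalize a raw measure matrix
#'
#' Divides every length/girth/angle column element-wise by the participant's
#' body height, making measures comparable across statures. Dimensionless
#' index columns (BMI, WHtR) are excluded from the division and kept as they
#' are, flagged by their registry kind. Rows with any missing retained value
#' are dropped with a message.
#'
#' @param x A `bt_measures` matrix in state `"raw"`.
#' @param heights Numeric vector of body heights, one per row of `x`, in the
#'   same unit as the measures (cm).
#' @return A `bt_measures` matrix in state `"height_normalized"`.
#' @export
height_normalize <- function(x, heights) {
  stopifnot(inherits(x, "bt_measures"))
  if (measure_state(x) != "raw")
    stop("height_normalize expects a raw matrix, got state ", measure_state(x))
  if (length(heights) != nrow(x))
    stop("need one height per participant")
  bad <- which(!is.finite(heights) | heights <= 0)
  if (length(bad))
    stop("non-positive height for participant(s): ",
         paste(rownames(x)[bad], collapse = ", "))
  reg <- measure_info(x)
  keep <- stats::complete.cases(unclass(x))
  if (!all(keep)) {
    message("dropping ", sum(!keep), " row(s) with missing measures")
    x <- unclass(x)[keep, , drop = FALSE]
    heights <- heights[keep]
  } else x <- unclass(x)
  divide <- reg$kind != "index"
  x[, divide] <- x[, divide, drop = FALSE] / heights
  new_measure_matrix(x, state = "height_normalized", registry = reg)
}

#' Z-normalize a height-normalized measure matrix
#'
#' Centers and scales each column to zero mean and unit standard deviation,
#' using the population (1/n) standard-deviation convention, computed over all
#' participants pooled across sexes (a per-sex option is available; pooling is
#' what makes male/female mean profiles interpretable as contrasts around the
#' cohort mean).
#'
#' @param x A `bt_measures` matrix in state `"height_normalized"`.
#' @param by_sex Optional factor/character of per-row sex labels; when given,
#'   columns are standardized within each sex separately.
#' @return A `bt_measures` matrix in state `"z_scored"`.
#' @export
z_normalize <- function(x, by_sex = NULL) {
  stopifnot(inherits(x, "bt_measures"))
  if (measure_state(x) != "z_scored" && measure_state(x) != "height_normalized")
    stop("z_normalize expects a height-normalized matrix, got state ",
         measure_state(x))
  if (measure_state(x) == "z_scored")
    stop("matrix is already z-scored")
  if (nrow(x) < 2) stop("need at least 2 participants to Z-normalize")
  reg <- measure_info(x)
  m <- unclass(x)
  strata <- if (is.null(by_sex)) rep("all", nrow(m)) else as.character(by_sex)
  for (s in unique(strata)) {
    i <- strata == s
    mu <- colMeans(m[i, , drop = FALSE])
    sd_pop <- sqrt(colMeans(sweep(m[i, , drop = FALSE], 2, mu)^2))
    zero <- which(sd_pop <= 0 | !is.finite(sd_pop))
    if (length(zero))
      stop("zero-variance column(s): ",
           paste(colnames(m)[zero], collapse = ", "))
    m[i, ] <- sweep(sweep(m[i, , drop = FALSE], 2, mu), 2, sd_pop, "/")
  }
  new_measure_matrix(m, state = "z_scored", registry = reg)
}
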