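#' Correlation of meta-measures with age
#'
#' Pearson correlation of each meta-measure score with participant age,
#' computed per sex. Zero-variance meta-measures are reported as `NA` with a
#' warning.
#'
#' @param meta Meta-measure score matrix (participants x meta-measures).
#' @param ages Numeric ages, one per row.
#' @param sexes Character sexes (`"F"`/`"M"`), one per row.
#' @return Matrix meta-measures x sexes of correlation coefficients.
#' @export
metameasure_age_correlation <- function(meta, ages, sexes) {
  stopifnot(nrow(meta) == length(ages), length(ages) == length(sexes))
  out <- sapply(c("F", "M"), function(s) {
    i <- sexes == s
    if (sum(i) < 3) stop("need at least 3 participants of sex ", s)
    apply(meta[i, , drop = FALSE], 2, function(v) {
      if (stats::sd(v) == 0) {
        warning("zero-variance meta-measure; correlation undefined")
        return(NA_real_)
      }
      stats::cor(v, ages[i])
    })
  })
  out
}

#' Mean meta-measure profile of a group (bodygram)
#'
#' The bodygram of a group is the per-axis arithmetic mean of its members'
#' meta-measure scores, in Z units; over the whole cohort it is zero on every
#' axis by construction of the Z matrix.
#'
#' @param meta Meta-measure score matrix.
#' @param ids Row names (participant ids) of the group; `NULL` for all rows.
#' @return Named numeric vector over the meta-measure axes.
#' @export
bodygram <- function(meta, ids = NULL) {
  m <- if (is.null(ids)) meta else {
    missing <- setdiff(ids, rownames(meta))
    if (length(missing)) stop("unknown participant id(s): ",
                              paste(utils::head(missing, 5), collapse = ", "))
    meta[ids, , drop = FALSE]
  }
  if (!nrow(m)) stop("empty group")
  colMeans(m)
}

#' Difference bodygram between two age strata
#'
#' Per-axis difference `mean(old) - mean(young)`; axes whose absolute change
#' exceeds `flag_threshold` (default 0.2 Z) are flagged as the most pronounced
#' aging changes.
#'
#' @param meta Meta-measure score matrix.
#' @param ids_young,ids_old Participant ids of the two strata.
#' @param flag_threshold Absolute-change flag threshold in Z units.
#' @return Named numeric vector of per-axis changes with logical attribute
#'   `"flagged"`.
#' @export
delta_bodygram <- function(meta, ids_young, ids_old, flag_threshold = 0.2) {
  delta <- bodygram(meta, ids_old) - bodygram(meta, ids_young)
  attr(delta, "flagged") <- abs(delta) > flag_threshold
  delta
}

#' Body-type incidence by age
#'
#' Within each sex and half-open age bin `[lo, hi)`, the percentage of
#' participants belonging to each body type. Empty bins are recorded as
#' missing, not zero.
#'
#' @param labels Named character vector of body-type labels (per participant).
#' @param participants Data frame with `id`, `sex`, `age`.
#' @param bin_width Age bin width in years (default 5).
#' @return Object of class `bt_incidence`: list per sex of a bins x types
#'   percentage matrix (attribute `"n"` holds per-bin counts).
#' @export
incidence_by_age <- function(labels, participants, bin_width = 5) {
  p <- participants[match(names(labels), participants$id), ]
  if (anyNA(p$id)) stop("labels contain ids absent from participants")
  lo <- floor(min(p$age) / bin_width) * bin_width
  hi <- ceiling((max(p$age) + 1e-9) / bin_width) * bin_width
  breaks <- seq(lo, hi, by = bin_width)
  bin <- cut(p$age, breaks = breaks, right = FALSE,
             labels = sprintf("[%g,%g)", breaks[-length(breaks)], breaks[-1]))
  out <- lapply(c("F", "M"), function(s) {
    i <- p$sex == s
    # keep only types observed in this sex
    tl <- sort(unique(labels[i]))
    tab <- table(bin[i], factor(labels[i], levels = tl))
    n <- rowSums(tab)
    pct <- sweep(unclass(tab), 1, n, "/") * 100
    pct[n == 0, ] <- NA_real_
    attr(pct, "n") <- n
    pct
  })
  names(out) <- c("F", "M")
  structure(out, class = "bt_incidence", bin_width = bin_width)
}

#' Net change of body-type incidence over the age range
#'
#' For each sex and type, the change in incidence between the latest and the
#' earliest age bin; the per-sex net change is the sum of the positive
#' changes, which (up to rounding) equals the sum of absolute negative ones
#' because percentages sum to 100 in every bin, and is reported as a
#' plus-minus percentage.
#'
#' @param inc A `bt_incidence` object.
#' @param mode `"sum_positive"` (default) or `"half_total_abs"` — the latter
#'   reports half the total absolute change, identical for conserved
#'   percentages.
#' @return List per sex with `delta` (per-type change) and `net` (the
#'   plus-minus percentage).
#' @export
net_incidence_change <- function(inc, mode = c("sum_positive",
                                               "half_total_abs")) {
  mode <- match.arg(mode)
  stopifnot(inherits(inc, "bt_incidence"))
  lapply(unclass(inc), function(pct) {
    ok <- !apply(pct, 1, function(r) all(is.na(r)))
    if (sum(ok) < 2) stop("need at least 2 occupied age bins")
    first <- pct[which(ok)[1], ]
    last <- pct[which(ok)[sum(ok)], ]
    if (anyNA(first) || anyNA(last)) stop("missing boundary bin")
    delta <- last - first
    net <- if (mode == "sum_positive") sum(delta[delta > 0])
           else sum(abs(delta)) / 2
    list(delta = delta, net = net)
  })
}

#' Smoothed index-versus-age curve of a body type
#'
#' Locally weighted regression (LOESS, degree 1, default span 0.5) of a body
#' index on age within one body type, evaluated on a one-year grid over the
#' type's observed age range. Requires at least 10 members spanning at least
#' two decades of age.
#'
#' @param index_values Index values (e.g. BMI) of the type members.
#' @param ages Ages of the same members.
#' @param span LOESS span.
#' @param type Type label used in error messages.
#' @return Data frame with columns `age` and `value`.
#' @export
smoothed_index_curve <- function(index_values, ages, span = 0.5,
                                 type = "type") {
  if (length(index_values) < 10 || diff(range(ages)) < 20)
    stop("insufficient data for smoothed curve of ", type,
         " (need >= 10 members spanning >= 2 decades)")
  fit <- stats::loess(index_values ~ ages, span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  grid <- seq(ceiling(min(ages)), floor(max(ages)), by = 1)
  data.frame(age = grid, value = stats::predict(fit, newdata =
                                                  data.frame(ages = grid)))
}
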