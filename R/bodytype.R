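#' Cluster participants into body types
#'
#' Runs k-means on the participants' meta-measure vectors and returns the raw
#' assignment; [label_types()] turns cluster ids into F/M/B labels ordered by
#' mean age. To avoid the local optima that plain random restarts fall into on
#' strongly clustered data, the search combines `nstart` random restarts with
#' one run initialized from the centroids of a Ward-linkage cut, and keeps the
#' solution with the lowest within-cluster sum of squares. Deterministic under
#' a fixed seed.
#'
#' @param meta Numeric matrix participants x meta-measures, as returned by
#'   [score_metameasures()].
#' @param k Number of body types (default 15).
#' @param nstart Number of random k-means restarts.
#' @param seed Seed for the restarts.
#' @return Integer vector of cluster ids, named by participant id, with the
#'   k-means fit in attribute `"fit"`.
#' @export
assign_body_types <- function(meta, k = 15L, nstart = 25L, seed = 1L) {
  stopifnot(is.matrix(meta), is.numeric(meta))
  if (k < 2) stop("k must be at least 2")
  if (k > nrow(meta)) stop("k exceeds the number of participants")
  set.seed(seed)
  fit <- stats::kmeans(meta, centers = k, nstart = nstart, iter.max = 100L)
  if (nrow(meta) <= 10000) {   # Ward tree needs the full distance matrix
    hc <- stats::hclust(stats::dist(meta), method = "ward.D2")
    grp <- stats::cutree(hc, k = k)
    cent <- apply(meta, 2, function(v) tapply(v, grp, mean))
    fit2 <- try(stats::kmeans(meta, centers = cent, iter.max = 100L),
                silent = TRUE)
    if (!inherits(fit2, "try-error") && fit2$tot.withinss < fit$tot.withinss)
      fit <- fit2
  }
  structure(stats::setNames(fit$cluster, rownames(meta)), fit = fit)
}

#' Select the number of body types by silhouette
#'
#' Scans candidate counts, clustering the participants by seeded k-means at
#' each `k` and scoring the partition by mean silhouette width over Euclidean
#' distances in meta-measure space; ties break toward the smallest `k`.
#'
#' @inheritParams assign_body_types
#' @param k_range Candidate cluster counts.
#' @return Selected `k` with the silhouette profile in attribute `"profile"`.
#' @export
auto_select_k_types <- function(meta, k_range = 5:25, nstart = 25L, seed = 1L) {
  k_range <- sort(unique(as.integer(k_range)))
  if (!length(k_range)) stop("empty k range")
  if (any(k_range < 2) || any(k_range > nrow(meta) - 1))
    stop("k range must lie within [2, participants - 1]")
  d <- stats::dist(meta)
  dm <- as.matrix(d)
  tree <- if (nrow(meta) <= 10000) stats::hclust(d, method = "ward.D2")
  sil <- vapply(k_range, function(k) {
    set.seed(seed)
    fit <- stats::kmeans(meta, centers = k, nstart = nstart, iter.max = 100L)
    if (!is.null(tree)) {   # Ward-initialized candidate, best inertia wins
      cent <- apply(meta, 2, function(v) tapply(v, stats::cutree(tree, k), mean))
      fit2 <- try(stats::kmeans(meta, centers = cent, iter.max = 100L),
                  silent = TRUE)
      if (!inherits(fit2, "try-error") && fit2$tot.withinss < fit$tot.withinss)
        fit <- fit2
    }
    mean(cluster::silhouette(fit$cluster, dmatrix = dm)[, "sil_width"])
  }, numeric(1))
  structure(k_range[which.max(sil)], profile = stats::setNames(sil, k_range))
}

#' Label body types by sex composition and mean age
#'
#' Types are labeled `F` if their female fraction reaches `purity` (default
#' 0.9), `M` if the male fraction does, and `B` (mixed) otherwise. Within each
#' letter class, indices are assigned in order of increasing mean member age
#' (F1 is the youngest female type). Labels depend only on composition and
#' mean age, never on the incoming cluster ids.
#'
#' @param assignment Cluster ids from [assign_body_types()].
#' @param participants Data frame with `id`, `sex` (`"F"`/`"M"`), `age`.
#' @param purity Sex-fraction threshold for calling a type female- or
#'   male-specific ("almost exclusively" one sex).
#' @return Object of class `bt_types`: list with `labels` (participant ->
#'   type label, named character vector) and `summary` (per-type label, size,
#'   mean age, sex fractions).
#' @export
label_types <- function(assignment, participants, purity = 0.9) {
  p <- participants[match(names(assignment), participants$id), ]
  if (anyNA(p$id)) stop("assignment contains ids absent from participants")
  ids <- sort(unique(assignment))
  info <- do.call(rbind, lapply(ids, function(cl) {
    i <- assignment == cl
    if (!any(i)) stop("empty body type: cluster ", cl)
    data.frame(cluster = cl, n = sum(i),
               mean_age = mean(p$age[i]),
               frac_f = mean(p$sex[i] == "F"),
               stringsAsFactors = FALSE)
  }))
  info$class <- ifelse(info$frac_f >= purity, "F",
                       ifelse(1 - info$frac_f >= purity, "M", "B"))
  info$label <- NA_character_
  for (cl in c("F", "M", "B")) {
    i <- which(info$class == cl)
    i <- i[order(info$mean_age[i])]
    info$label[i] <- paste0(cl, seq_along(i))
  }
  labels <- stats::setNames(info$label[match(assignment, info$cluster)],
                            names(assignment))
  structure(list(labels = labels,
                 summary = info[order(info$label),
                                c("label", "cluster", "n", "mean_age",
                                  "frac_f")]),
            class = "bt_types")
}

#' Split mixed-sex types into sex-specific views
#'
#' Mixed (`B`) body types are considered separately for women and men in all
#' downstream statistics; this returns per-participant labels where `B1`
#' becomes `B1F` / `B1M` and so on, while F and M types are unchanged.
#'
#' @param types A `bt_types` object.
#' @param participants Data frame with `id` and `sex`.
#' @return Named character vector of analysis labels.
#' @export
split_mixed_types <- function(types, participants) {
  lab <- types$labels
  sex <- participants$sex[match(names(lab), participants$id)]
  mixed <- startsWith(lab, "B")
  lab[mixed] <- paste0(lab[mixed], sex[mixed])
  lab
}

#' Age-matched, sex-specific reference group for a body type
#'
#' Collects all same-sex participants whose age lies within a ten-year window
#' centred on the type's median member age, independent of their own body
#' type (members of the type itself are included). Window half-open:
#' `[median - w/2, median + w/2)`.
#'
#' @param type_ids Participant ids belonging to the type.
#' @param participants Data frame with `id`, `sex`, `age`.
#' @param window_years Width of the age window (default 10).
#' @return Character vector of reference participant ids.
#' @export
build_reference_group <- function(type_ids, participants, window_years = 10) {
  if (!length(type_ids)) stop("empty body type")
  p <- participants
  members <- p[p$id %in% type_ids, ]
  # sex-specific reference: the type's majority sex (F- and M-types may carry
  # a small minority of the other sex below the purity threshold)
  sex <- names(sort(table(members$sex), decreasing = TRUE))[1]
  members <- members[members$sex == sex, ]
  center <- stats::median(members$age)
  lo <- center - window_years / 2; hi <- center + window_years / 2
  ref <- p$id[p$sex == sex & p$age >= lo & p$age < hi]
  if (!length(ref)) stop("empty reference group for window [", lo, ", ", hi, ")")
  ref
}

#' Rank-sum comparison of a type feature against its reference
#'
#' Two-sided Wilcoxon rank-sum test of the feature values of a body type
#' against its age-matched reference group, reported as a tiered significance
#' mark: `+`/`-` for p < 0.1, `++`/`--` for p < 0.01, `+++`/`---` for
#' p < 0.001, direction by the sign of the median difference.
#'
#' @param type_values Feature values of the type members.
#' @param ref_values Feature values of the reference group.
#' @return Object of class `bt_mark`: list with `p`, `direction` (`"+"`,
#'   `"-"` or `""`), `tier` (0--3) and `mark` (rendered string).
#' @export
compare_to_reference <- function(type_values, ref_values) {
  if (!length(type_values) || !length(ref_values))
    stop("both groups must be nonempty")
  if (length(unique(c(type_values, ref_values))) < 2) {
    warning("all values tied; no significance mark")
    return(structure(list(p = NA_real_, direction = "", tier = 0L, mark = ""),
                     class = "bt_mark"))
  }
  p <- suppressWarnings(
    stats::wilcox.test(type_values, ref_values, exact = FALSE)$p.value)
  dir <- if (stats::median(type_values) > stats::median(ref_values)) "+" else "-"
  tier <- significance_tier(p)
  mark <- if (tier > 0) strrep(dir, tier) else ""
  structure(list(p = p, direction = if (tier > 0) dir else "", tier = tier,
                 mark = mark),
            class = "bt_mark")
}

#' Significance tier of a p value
#'
#' Tier 3 for p < 0.001, tier 2 for p < 0.01, tier 1 for p < 0.1, 0 otherwise.
#'
#' @param p P value.
#' @return Integer tier 0--3.
#' @export
significance_tier <- function(p) {
  if (is.na(p)) return(0L)
  if (p < 0.001) 3L else if (p < 0.01) 2L else if (p < 0.1) 1L else 0L
}

#' @export
print.bt_types <- function(x, ...) {
  cat("<bt_types>", nrow(x$summary), "body types\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' @export
print.bt_mark <- function(x, ...) {
  cat(if (nzchar(x$mark)) x$mark else "(ns)",
      " p=", format.pval(x$p, digits = 3), "\n", sep = "")
  invisible(x)
}
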