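#' Derive meta-measures by clustering correlated measures
#'
#' Partitions the Z-scored measures into `k` meta-measures, each a cluster of
#' correlated single measures. The default route trains a small two-dimensional
#' self-organizing map on the transposed matrix (measures as items), cuts the
#' codebook into `k` groups by agglomerative clustering with correlation
#' distance, and assigns each measure the group of its best-matching unit. The
#' `"hclust"` route clusters the measures directly (average linkage, distance
#' `1 - Pearson correlation` between measure columns); on well-separated block
#' data both routes yield the same partition. Derived index columns (BMI,
#' WHtR) are by default excluded from the partitioning and attached afterwards
#' to their maximally correlated cluster, since they are computed from — and
#' thus trivially collinear with — the measures themselves.
#'
#' Cluster labels A--M are assigned by maximal member overlap with the
#' canonical meta-measure groups of [block_member_names()]; unmatched clusters
#' get numeric labels.
#'
#' @param z A `bt_measures` matrix in state `"z_scored"`.
#' @param k Number of meta-measures (default 13).
#' @param method `"som"` (default) or `"hclust"`.
#' @param cluster_indices Cluster index columns alongside the scanner measures
#'   instead of attaching them post hoc.
#' @param som_dim SOM grid side length (default 8, i.e. an 8x8 map).
#' @param seed Seed for the SOM initialization.
#' @return Object of class `bt_metadef`: list with `k`, `clusters` (label ->
#'   member names), `method`.
#' @export
derive_metameasures <- function(z, k = 13L, method = c("som", "hclust"),
                                cluster_indices = FALSE, som_dim = 8L,
                                seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(z, "bt_measures"))
  if (measure_state(z) != "z_scored")
    stop("derive_metameasures expects a z_scored matrix")
  reg <- measure_info(z)
  idx_cols <- colnames(z)[reg$kind == "index"]
  cl_cols <- if (cluster_indices) colnames(z) else setdiff(colnames(z), idx_cols)
  if (k < 1 || k > length(cl_cols))
    stop("k must lie between 1 and the number of clustered measures (",
         length(cl_cols), ")")
  m <- unclass(z)[, cl_cols, drop = FALSE]

  part <- if (k == 1L) {
    stats::setNames(rep(1L, ncol(m)), colnames(m))
  } else if (method == "hclust") {
    hclust_partition(m, k)
  } else {
    som_partition(m, k, som_dim, seed)
  }

  if (!cluster_indices && length(idx_cols)) {
    cm <- stats::cor(unclass(z)[, idx_cols, drop = FALSE], m)
    for (ic in idx_cols) {
      by_cl <- tapply(abs(cm[ic, ]), part[colnames(m)], mean)
      part[ic] <- as.integer(names(which.max(by_cl)))
    }
  }
  clusters <- split(names(part), part)
  names(clusters) <- label_metameasure_clusters(clusters)
  clusters <- clusters[order(names(clusters))]
  structure(list(k = as.integer(k), clusters = clusters, method = method),
            class = "bt_metadef")
}

# average-linkage clustering of measures under correlation distance
hclust_partition <- function(m, k) {
  d <- stats::as.dist(1 - stats::cor(m))
  stats::cutree(stats::hclust(d, method = "average"), k = k)
}

# SOM route: map measures onto a 2-D codebook, then cluster the codebook
som_partition <- function(m, k, som_dim, seed) {
  set.seed(seed)
  items <- t(m)                                    # measures as items
  # the map cannot have more units than items
  som_dim <- max(2L, min(som_dim, floor(sqrt(nrow(items)))))
  grid <- class::somgrid(som_dim, som_dim, "rectangular")
  map <- class::batchSOM(items, grid, radii = seq(som_dim / 2, 0,
                                                  length.out = 20))
  # best-matching unit per measure
  d2 <- outer(rowSums(items^2), rowSums(map$codes^2), `+`) -
    2 * items %*% t(map$codes)
  bmu <- max.col(-d2, ties.method = "first")
  # cut occupied codebook units by correlation distance between code vectors
  used <- sort(unique(bmu))
  codes <- map$codes[used, , drop = FALSE]
  if (length(used) < k)
    stop("SOM collapsed to fewer occupied units (", length(used),
         ") than requested clusters (", k, ")")
  dc <- stats::as.dist(1 - stats::cor(t(codes)))
  unit_cl <- stats::cutree(stats::hclust(dc, method = "average"), k = k)
  stats::setNames(unit_cl[match(bmu, used)], rownames(items))
}

# label clusters by maximal overlap with the canonical groups; greedy, with
# numeric fallbacks for unmatched clusters
label_metameasure_clusters <- function(clusters) {
  canon <- block_member_names()
  canon$B <- c(canon$B, "bmi", "whtr")
  ov <- vapply(clusters, function(cl)
    vapply(canon, function(g) length(intersect(cl, g)), numeric(1)),
    numeric(length(canon)))
  ov <- matrix(ov, nrow = length(canon),
               dimnames = list(names(canon), names(clusters)))
  labels <- rep(NA_character_, length(clusters))
  repeat {
    if (all(ov <= 0)) break
    best <- arrayInd(which.max(ov), dim(ov))
    labels[best[2]] <- rownames(ov)[best[1]]
    ov[best[1], ] <- -1; ov[, best[2]] <- -1
  }
  labels[is.na(labels)] <- as.character(seq_len(sum(is.na(labels))))
  labels
}

#' Score participants on the meta-measures
#'
#' Each meta-measure score is the unweighted arithmetic mean of its member
#' measures' Z values, so scores stay in Z units and the cohort-wide mean of
#' every meta-measure is approximately zero.
#'
#' @param z A `bt_measures` matrix in state `"z_scored"`.
#' @param def A `bt_metadef` from [derive_metameasures()].
#' @return Numeric matrix participants x meta-measures (labels as colnames).
#' @export
score_metameasures <- function(z, def) {
  stopifnot(inherits(z, "bt_measures"), inherits(def, "bt_metadef"))
  if (measure_state(z) != "z_scored")
    stop("score_metameasures expects a z_scored matrix")
  missing <- setdiff(unlist(def$clusters), colnames(z))
  if (length(missing))
    stop("definition references absent column(s): ",
         paste(missing, collapse = ", "))
  out <- vapply(def$clusters, function(cl)
    rowMeans(unclass(z)[, cl, drop = FALSE]), numeric(nrow(z)))
  out <- matrix(out, nrow = nrow(z),
                dimnames = list(rownames(z), names(def$clusters)))
  out
}

#' Select the number of meta-measures by silhouette
#'
#' Scans a range of cluster counts, partitioning the measures by average-
#' linkage correlation-distance clustering at each `k`, and returns the `k`
#' maximizing the mean silhouette width (ties broken toward the smallest `k`).
#'
#' @param z A `bt_measures` matrix in state `"z_scored"`.
#' @param k_range Integer vector of candidate cluster counts.
#' @return Selected `k`, with the full silhouette profile in attribute
#'   `"profile"`.
#' @export
auto_select_k <- function(z, k_range = 2:20) {
  stopifnot(inherits(z, "bt_measures"))
  if (measure_state(z) != "z_scored")
    stop("auto_select_k expects a z_scored matrix")
  reg <- measure_info(z)
  cl_cols <- colnames(z)[reg$kind != "index"]
  k_range <- sort(unique(as.integer(k_range)))
  if (!length(k_range)) stop("empty k range")
  if (any(k_range < 2) || any(k_range > length(cl_cols)))
    stop("k range must lie within [2, number of measures]")
  m <- unclass(z)[, cl_cols, drop = FALSE]
  dm <- as.matrix(stats::as.dist(1 - stats::cor(m)))
  tree <- stats::hclust(stats::as.dist(dm), method = "average")
  sil <- vapply(k_range, function(k) {
    if (k >= ncol(m)) return(0)   # all-singleton partition scores zero
    cl <- stats::cutree(tree, k = k)
    mean(cluster::silhouette(cl, dmatrix = dm)[, "sil_width"])
  }, numeric(1))
  best <- k_range[which.max(sil)]   # which.max takes the first (smallest) tie
  structure(best, profile = stats::setNames(sil, k_range))
}

#' @export
print.bt_metadef <- function(x, ...) {
  cat("<bt_metadef> ", x$k, " meta-measures (", x$method, "):\n", sep = "")
  for (nm in names(x$clusters))
    cat("  ", nm, ": ", length(x$clusters[[nm]]), " measures\n", sep = "")
  invisible(x)
}
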