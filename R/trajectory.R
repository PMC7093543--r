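#' Similarity-link rule
#'
#' Configures how "most similar" participant pairs are selected from the
#' Euclidean distances in meta-measure space. The default is a
#' nearest-neighbour rule: each participant selects its `m` nearest
#' neighbours (ties broken by participant order, deterministic) and a pair is
#' a link if either side selects the other. The `"quantile"` alternative links
#' all pairs whose distance falls below the given quantile of all pairwise
#' distances.
#'
#' @param method `"knn"` or `"quantile"`.
#' @param m Neighbours per participant (knn rule).
#' @param q Distance quantile (quantile rule).
#' @return A `bt_linkrule` list.
#' @export
link_rule <- function(method = c("knn", "quantile"), m = 3L, q = 0.01) {
  method <- match.arg(method)
  structure(list(method = method, m = as.integer(m), q = q),
            class = "bt_linkrule")
}

# undirected link pairs (two-column index matrix, i < j) under a rule
similarity_link_pairs <- function(meta, rule) {
  n <- nrow(meta)
  dm <- as.matrix(stats::dist(meta))
  if (rule$method == "knn") {
    if (n < rule$m + 1)
      stop("need at least m + 1 = ", rule$m + 1, " participants")
    sel <- lapply(seq_len(n), function(i) {
      ord <- order(dm[i, -i])              # ties break by participant order
      cand <- seq_len(n)[-i][ord]
      cand[seq_len(rule$m)]
    })
    pairs <- do.call(rbind, lapply(seq_len(n), function(i)
      cbind(pmin(i, sel[[i]]), pmax(i, sel[[i]]))))
    unique(pairs)
  } else {
    d <- dm[upper.tri(dm)]
    thr <- stats::quantile(d, rule$q)
    idx <- which(upper.tri(dm) & dm <= thr, arr.ind = TRUE)
    cbind(idx[, 1], idx[, 2])
  }
}

#' Count similarity links between body types
#'
#' Computes Euclidean distances between all participant pairs in meta-measure
#' space, selects the most similar pairs under the configured rule, and
#' tallies them by the pair of body types involved. The result is a symmetric
#' type-by-type count matrix; the diagonal holds within-type links, which are
#' counted but excluded from transition reporting.
#'
#' @param meta Meta-measure score matrix with participant rownames.
#' @param labels Named character vector of body-type labels.
#' @param rule A [link_rule()].
#' @return Symmetric numeric matrix of link counts with type labels as
#'   dimnames and the link pair ids in attribute `"pairs"`.
#' @export
count_similarity_links <- function(meta, labels, rule = link_rule()) {
  labels <- labels[rownames(meta)]
  if (anyNA(labels)) stop("labels must cover all rows of meta")
  pairs <- similarity_link_pairs(meta, rule)
  tl <- sort(unique(labels))
  lm <- matrix(0, length(tl), length(tl), dimnames = list(tl, tl))
  if (nrow(pairs)) {
    a <- labels[pairs[, 1]]; b <- labels[pairs[, 2]]
    for (k in seq_along(a)) {
      lm[a[k], b[k]] <- lm[a[k], b[k]] + 1
      if (a[k] != b[k]) lm[b[k], a[k]] <- lm[b[k], a[k]] + 1
    }
  }
  attr(lm, "pairs") <- cbind(rownames(meta)[pairs[, 1]],
                             rownames(meta)[pairs[, 2]])
  lm
}

#' Age-stratified similarity links
#'
#' Counts similarity links separately within each age bin (a link is counted
#' only when both members fall in the bin). Bins with fewer participants than
#' the rule requires are returned as empty matrices and flagged.
#'
#' @inheritParams count_similarity_links
#' @param ages Named numeric ages (per participant).
#' @param breaks Age bin breaks (half-open `[lo, hi)`).
#' @return Named list of link matrices, one per bin; empty bins carry
#'   attribute `"empty" = TRUE`.
#' @export
stratify_links_by_age <- function(meta, labels, ages, rule = link_rule(),
                                  breaks = seq(40, 80, by = 10)) {
  ages <- ages[rownames(meta)]
  bins <- cut(ages, breaks = breaks, right = FALSE,
              labels = sprintf("[%g,%g)", breaks[-length(breaks)],
                               breaks[-1]))
  out <- lapply(levels(bins), function(b) {
    i <- which(!is.na(bins) & bins == b)
    min_n <- if (rule$method == "knn") rule$m + 1 else 2
    if (length(i) < min_n) {
      tl <- sort(unique(labels[rownames(meta)]))
      m <- matrix(0, length(tl), length(tl), dimnames = list(tl, tl))
      return(structure(m, empty = TRUE))
    }
    count_similarity_links(meta[i, , drop = FALSE], labels, rule)
  })
  stats::setNames(out, levels(bins))
}

#' Differential meta-measure profile along a link
#'
#' For two body types A and B, the mean meta-measure profile of B's linked
#' members minus that of A's linked members, restricted to the participants
#' actually involved in A--B links; it characterizes what changes along the
#' candidate transition.
#'
#' @param meta Meta-measure score matrix.
#' @param labels Named type labels.
#' @param type_a,type_b The two types (must differ).
#' @param rule A [link_rule()].
#' @return Named numeric vector over the meta-measure axes.
#' @export
link_differential_profile <- function(meta, labels, type_a, type_b,
                                      rule = link_rule()) {
  if (type_a == type_b) stop("types must differ")
  lm <- count_similarity_links(meta, labels, rule)
  pairs <- attr(lm, "pairs")
  la <- labels[pairs[, 1]]; lb <- labels[pairs[, 2]]
  ab <- (la == type_a & lb == type_b) | (la == type_b & lb == type_a)
  if (!any(ab)) stop("no links between ", type_a, " and ", type_b)
  side_a <- unique(c(pairs[ab & la == type_a, 1], pairs[ab & lb == type_a, 2]))
  side_b <- unique(c(pairs[ab & la == type_b, 1], pairs[ab & lb == type_b, 2]))
  bodygram(meta, side_b) - bodygram(meta, side_a)
}

#' Transition graph from a link matrix
#'
#' Keeps the off-diagonal link counts at or above a configurable quantile of
#' the nonzero cells (default: the top half), directs each retained edge from
#' the type with the lower mean age to the higher one (ties broken toward the
#' higher mean BMI), and weights it by the link count. Node coordinates are
#' (mean age, mean BMI), mirroring an age-versus-BMI layout.
#'
#' @param lm Symmetric link-count matrix from [count_similarity_links()].
#' @param summaries Data frame with `label`, `mean_age`, `mean_bmi` per type.
#' @param count_quantile Quantile of nonzero off-diagonal counts below which
#'   edges are dropped.
#' @return Data frame edge list (`from`, `to`, `weight`) with the node table
#'   in attribute `"nodes"`; empty (with a warning) when no edge passes.
#' @export
transition_graph <- function(lm, summaries, count_quantile = 0.5) {
  tl <- rownames(lm)
  s <- summaries[match(tl, summaries$label), ]
  if (anyNA(s$label)) stop("summaries must cover all types in the link matrix")
  ut <- upper.tri(lm)
  counts <- lm[ut]
  nz <- counts[counts > 0]
  edges <- data.frame(from = character(0), to = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE)
  if (length(nz)) {
    thr <- stats::quantile(nz, count_quantile)
    idx <- which(ut & lm >= thr & lm > 0, arr.ind = TRUE)
    if (nrow(idx)) {
      from <- tl[idx[, 1]]; to <- tl[idx[, 2]]
      swap <- s$mean_age[idx[, 1]] > s$mean_age[idx[, 2]] |
        (s$mean_age[idx[, 1]] == s$mean_age[idx[, 2]] &
           s$mean_bmi[idx[, 1]] > s$mean_bmi[idx[, 2]])
      tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
      edges <- data.frame(from = from, to = to,
                          weight = lm[cbind(idx[, 1], idx[, 2])],
                          stringsAsFactors = FALSE)
      edges <- edges[order(-edges$weight), ]
      rownames(edges) <- NULL
    }
  }
  if (!nrow(edges)) warning("no edges above threshold; empty transition graph")
  attr(edges, "nodes") <- s[, c("label", "mean_age", "mean_bmi")]
  edges
}
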