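# similarity links, age stratification, differential profiles, transitions

test_that("nearest-neighbour links match brute-force enumeration at small n", {
  set.seed(31)
  n <- 50
  meta <- matrix(rnorm(n * 4), n, 4,
                 dimnames = list(sprintf("P%02d", 1:n), letters[1:4]))
  labels <- setNames(sample(c("X", "Y", "Z"), n, replace = TRUE),
                     rownames(meta))
  m <- 3
  # independent oracle: exhaustive pairwise distances, union-kNN rule
  dm <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    dm[i, j] <- sqrt(sum((meta[i, ] - meta[j, ])^2))
  linked <- matrix(FALSE, n, n)
  for (i in 1:n) {
    nb <- setdiff(order(dm[i, ]), i)[1:m]
    linked[i, nb] <- TRUE
  }
  linked <- linked | t(linked)
  oracle <- matrix(0, 3, 3, dimnames = list(c("X", "Y", "Z"),
                                            c("X", "Y", "Z")))
  for (i in 1:(n - 1)) for (j in (i + 1):n) if (linked[i, j]) {
    a <- labels[i]; b <- labels[j]
    oracle[a, b] <- oracle[a, b] + 1
    if (a != b) oracle[b, a] <- oracle[b, a] + 1
  }
  lm <- count_similarity_links(meta, labels, link_rule(m = m))
  expect_equal(unclass(lm)[rownames(oracle), colnames(oracle)],
               oracle, ignore_attr = TRUE)
})

test_that("link matrices are symmetric and invariant to id relabeling", {
  fx <- fixture_clusters(n_per = 40,
                         centers = list(c(0, 0), c(2, 0), c(0, 2)),
                         spread = 0.8, seed = 5)
  lm <- count_similarity_links(fx$meta, fx$labels)
  expect_equal(unclass(lm), t(unclass(lm)), ignore_attr = TRUE)
  expect_true(all(lm >= 0))
  # permuting participant order leaves the counts unchanged
  perm <- sample(nrow(fx$meta))
  lm2 <- count_similarity_links(fx$meta[perm, ], fx$labels)
  expect_equal(unclass(lm2), unclass(lm), ignore_attr = TRUE)
})

test_that("well-separated types share no links; quantile rule agrees on geometry", {
  fx <- fixture_clusters(n_per = 40, centers = list(c(0, 0), c(5, 0)),
                         spread = 0.1)
  lm <- count_similarity_links(fx$meta, fx$labels)
  expect_equal(lm["T1", "T2"], 0)
  expect_gt(lm["T1", "T1"], 0)
  lmq <- count_similarity_links(fx$meta, fx$labels,
                                link_rule("quantile", q = 0.01))
  expect_equal(lmq["T1", "T2"], 0)
  expect_error(count_similarity_links(fx$meta[1:3, ], fx$labels),
               "at least m \\+ 1")
})

test_that("age stratification is consistent and localizes planted overlap", {
  # types X and Y overlap only among the young
  set.seed(13)
  n <- 300
  age <- runif(n, 40, 80)
  young <- age < 60
  x_off <- ifelse(young, 0.5, 4)
  type <- rep(c("X", "Y"), length.out = n)
  meta <- cbind(rnorm(n, ifelse(type == "X", 0, x_off), 0.5), rnorm(n, 0, 0.5))
  rownames(meta) <- sprintf("P%03d", 1:n)
  labels <- setNames(type, rownames(meta))
  ages <- setNames(age, rownames(meta))
  strat <- stratify_links_by_age(meta, labels, ages,
                                 breaks = c(40, 60, 80))
  xy_young <- strat[["[40,60)"]]["X", "Y"]
  xy_old <- strat[["[60,80)"]]["X", "Y"]
  expect_gt(xy_young, 5 * max(1, xy_old))
  # a single bin spanning all ages reproduces the unstratified count
  single <- stratify_links_by_age(meta, labels, ages, breaks = c(40, 81))
  full <- count_similarity_links(meta, labels)
  expect_equal(unclass(single[[1]]), unclass(full), ignore_attr = TRUE)
})

test_that("null calibration: random type splits give flat link frequencies", {
  set.seed(99)
  pvals <- replicate(100, {
    n <- 500
    meta <- matrix(rnorm(n * 13), n,
                   dimnames = list(sprintf("P%03d", 1:n), LETTERS[1:13]))
    labels <- setNames(sample(rep(paste0("T", 1:4), length.out = n)),
                       rownames(meta))
    lm <- count_similarity_links(meta, labels)
    ns <- table(labels)[rownames(lm)]
    np <- outer(ns, ns)
    diag(np) <- ns * (ns - 1) / 2
    p <- np[upper.tri(np, diag = TRUE)]
    counts <- lm[upper.tri(lm, diag = TRUE)]
    suppressWarnings(chisq.test(counts, p = p / sum(p))$p.value)
  })
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("link differential profiles recover planted axis offsets", {
  set.seed(21)
  n <- 80
  metaA <- cbind(rnorm(n, 0, 0.4), rnorm(n, 0, 0.4), rnorm(n, 0, 0.4))
  metaB <- sweep(cbind(rnorm(n, 0, 0.4), rnorm(n, 0, 0.4),
                       rnorm(n, 0, 0.4)), 2, c(0, 1, 0), "+")
  meta <- rbind(metaA, metaB)
  colnames(meta) <- c("A", "B", "C")
  rownames(meta) <- sprintf("P%03d", 1:(2 * n))
  labels <- setNames(rep(c("TA", "TB"), each = n), rownames(meta))
  d <- link_differential_profile(meta, labels, "TA", "TB")
  # links connect the most similar individuals, so the profile measures the
  # small step along the transition: the planted offset is strongly
  # attenuated but recovered on the correct axis with the correct sign
  expect_gt(d[["B"]], 0.1)
  expect_equal(names(which.max(abs(d))), "B")   # planted axis dominates
  # antisymmetry under swapping the two types
  expect_equal(unname(d),
               unname(-link_differential_profile(meta, labels, "TB", "TA")))
  expect_error(link_differential_profile(meta, labels, "TA", "TA"), "differ")
  # isolated types have no links to profile
  fx <- fixture_clusters(n_per = 30, centers = list(c(0, 0), c(9, 9)),
                         spread = 0.05)
  expect_error(link_differential_profile(fx$meta, fx$labels, "T1", "T2"),
               "no links")
})

test_that("transition graphs order a planted chain by age and break ties by BMI", {
  set.seed(77)
  n <- 90
  centers <- c(0, 1.2, 2.4)       # consecutive overlap X-Y and Y-Z only
  meta <- cbind(rnorm(3 * n, rep(centers, each = n), 0.35),
                rnorm(3 * n, 0, 0.35))
  rownames(meta) <- sprintf("P%03d", 1:(3 * n))
  labels <- setNames(rep(c("X", "Y", "Z"), each = n), rownames(meta))
  lm <- count_similarity_links(meta, labels)
  summaries <- data.frame(label = c("X", "Y", "Z"),
                          mean_age = c(45, 55, 65),
                          mean_bmi = c(24, 26, 28))
  g <- transition_graph(lm, summaries, count_quantile = 0)
  edge <- function(a, b) any(g$from == a & g$to == b)
  expect_true(edge("X", "Y"))
  expect_true(edge("Y", "Z"))
  expect_false(edge("Z", "X") || edge("X", "Z"))
  expect_false(any(g$to == "X"))   # youngest type is never a destination
  # fully isolated archetypes give an empty graph with a warning
  fx <- fixture_clusters(n_per = 40, centers = list(c(0, 0), c(9, 9)),
                         spread = 0.05)
  lm0 <- count_similarity_links(fx$meta, fx$labels)
  s0 <- data.frame(label = c("T1", "T2"), mean_age = c(50, 60),
                   mean_bmi = c(24, 28))
  expect_warning(g0 <- transition_graph(lm0, s0), "empty")
  expect_equal(nrow(g0), 0L)
  # equal mean ages: direction toward the higher mean BMI
  s_tie <- data.frame(label = c("X", "Y", "Z"), mean_age = c(50, 50, 50),
                      mean_bmi = c(28, 24, 26))
  g_tie <- transition_graph(lm, s_tie, count_quantile = 0)
  expect_true(any(g_tie$from == "Y" & g_tie$to == "X"))
})
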