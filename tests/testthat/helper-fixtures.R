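# shared fixtures, built once per suite run and cached

.fixtures <- new.env(parent = emptyenv())

# mid-size default cohort taken through the full measure pipeline
fixture_pipeline <- function(n = 400L, seed = 303L) {
  key <- sprintf("pipe_%d_%d", n, seed)
  if (is.null(.fixtures[[key]])) {
    cfg <- generator_config(n_male = n, n_female = n, seed = seed)
    coh <- generate_cohort(cfg)
    p <- coh$participants
    z <- z_normalize(height_normalize(select_measures(coh$measures), p$height))
    def <- derive_metameasures(z, 13, seed = seed)
    meta <- score_metameasures(z, def)
    .fixtures[[key]] <- list(cfg = cfg, coh = coh, p = p, z = z, def = def,
                             meta = meta)
  }
  .fixtures[[key]]
}

# well-separated synthetic meta-measure clusters for geometry tests
fixture_clusters <- function(n_per = 30L, centers = list(c(0, 0), c(5, 0)),
                             spread = 0.1, seed = 1L) {
  set.seed(seed)
  m <- do.call(rbind, lapply(centers, function(ct)
    cbind(rnorm(n_per, ct[1], spread), rnorm(n_per, ct[2], spread))))
  rownames(m) <- sprintf("P%03d", seq_len(nrow(m)))
  colnames(m) <- c("A", "B")
  labels <- setNames(rep(paste0("T", seq_along(centers)), each = n_per),
                     rownames(m))
  list(meta = m, labels = labels)
}

# adjusted Rand index between two labelings (independent oracle, standard
# contingency-table formula)
helper_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_index <- si * sj / n2
  (sij - exp_index) / ((si + sj) / 2 - exp_index)
}

# minimal z-scored measure matrix around a planted block structure, for
# small-instance clustering tests
helper_block_z <- function(n, blocks, within = 0.8, cross = 0.2, seed = 1L) {
  set.seed(seed)
  labs <- rep(seq_along(blocks), blocks)
  nm <- sprintf("m%02d", seq_along(labs))
  G <- rnorm(n)
  B <- matrix(rnorm(n * length(blocks)), n, length(blocks))
  m <- sapply(seq_along(labs), function(j)
    sqrt(cross) * G + sqrt(within - cross) * B[, labs[j]] +
      sqrt(1 - within) * rnorm(n))
  colnames(m) <- nm
  rownames(m) <- sprintf("P%04d", seq_len(n))
  reg <- data.frame(name = nm, block = LETTERS[labs], kind = "girth",
                    retained = TRUE, height_scaled = TRUE,
                    mean_m = 50, sd_m = 5, mean_f = 48, sd_f = 5,
                    stringsAsFactors = FALSE)
  z <- z_normalize(new_measure_matrix(m, "height_normalized", reg))
  list(z = z, planted = setNames(LETTERS[labs], nm))
}
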