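#' Write a cohort as plain-text tables
#'
#' Writes `measures.csv` (id, sex, age, height, weight plus all measure
#' columns), `activity.csv`, `health.csv`, and a YAML sidecar
#' (`cohort_meta.yaml`) recording the generator seed, sample sizes and the
#' normalization state of the measure table.
#'
#' @param cohort A `bt_cohort`.
#' @param activity,health Optional record tables to write alongside.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_tables <- function(cohort, dir, activity = NULL, health = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- cohort$participants
  tab <- cbind(p[, c("id", "sex", "age", "height", "weight")],
               as.data.frame(unclass(cohort$measures)))
  utils::write.csv(tab, file.path(dir, "measures.csv"), row.names = FALSE)
  if (!is.null(activity))
    utils::write.csv(activity, file.path(dir, "activity.csv"),
                     row.names = FALSE)
  if (!is.null(health))
    utils::write.csv(health, file.path(dir, "health.csv"), row.names = FALSE)
  meta <- list(seed = cohort$config$seed,
               n_male = cohort$config$n_male,
               n_female = cohort$config$n_female,
               state = measure_state(cohort$measures))
  yaml::write_yaml(meta, file.path(dir, "cohort_meta.yaml"))
  invisible(dir)
}

#' Read a cohort from plain-text tables
#'
#' Reads the tables written by [write_cohort_tables()] (or equivalently
#' structured CSVs) back into a `bt_cohort`, with schema validation: required
#' columns present, sexes in `{F, M}`, numeric measures (locale problems such
#' as comma decimal separators are reported, never silently coerced), unique
#' participant ids.
#'
#' @param dir Directory containing `measures.csv` and optionally
#'   `activity.csv` / `health.csv`.
#' @param registry Measure registry describing the expected measure columns.
#' @return A list with `cohort`, `activity` (or `NULL`), `health` (or
#'   `NULL`).
#' @export
read_cohort_tables <- function(dir, registry = measure_registry()) {
  path <- file.path(dir, "measures.csv")
  if (!file.exists(path)) stop("missing measures.csv in ", dir)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "sex", "age", "height", "weight")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("measures.csv lacks column(s): ", paste(missing, collapse = ", "))
  dup <- tab$id[duplicated(tab$id)]
  if (length(dup))
    stop("duplicated participant id(s): ", paste(unique(dup), collapse = ", "))
  if (!all(tab$sex %in% c("F", "M")))
    stop("sex must be 'F' or 'M' (rows ",
         paste(utils::head(which(!tab$sex %in% c("F", "M")), 5),
               collapse = ", "), ")")
  mcols <- intersect(registry$name, names(tab))
  if (!length(mcols)) stop("no known measure columns found")
  for (cn in c("age", "height", "weight", mcols)) {
    if (!is.numeric(tab[[cn]])) {
      bad <- utils::head(which(is.na(suppressWarnings(
        as.numeric(tab[[cn]])))), 5)
      stop("non-numeric values in column ", cn, " (rows ",
           paste(bad, collapse = ", "),
           "); if decimals use commas, re-export with '.' decimal separator")
    }
  }
  m <- as.matrix(tab[, mcols, drop = FALSE])
  rownames(m) <- tab$id
  participants <- tab[, need]
  participants$archetype <- NA_character_
  cohort <- structure(
    list(participants = participants,
         measures = new_measure_matrix(m, state = "raw", registry = registry),
         config = NULL),
    class = "bt_cohort")
  read_opt <- function(f) {
    fp <- file.path(dir, f)
    if (file.exists(fp)) utils::read.csv(fp, stringsAsFactors = FALSE) else NULL
  }
  list(cohort = cohort, activity = read_opt("activity.csv"),
       health = read_opt("health.csv"))
}

#' Run the full body-typing pipeline
#'
#' Orchestrates the stages end to end: (optionally) simulate a cohort, select
#' and normalize measures, derive and score meta-measures, cluster and label
#' body types, and compute the aging, trajectory and health summaries. All
#' numeric outputs are fully determined by the configuration and seed. When
#' `out_dir` is given, stage outputs are written as CSV/TSV together with a
#' YAML run manifest.
#'
#' @param cohort A `bt_cohort`, or `NULL` to generate one from `config`.
#' @param config Generator configuration (used when `cohort` is `NULL` and
#'   recorded in the manifest).
#' @param activity,health Optional externally supplied day/health records;
#'   when the cohort is generated here they are simulated from the same
#'   configuration.
#' @param k_metameasures,k_bodytypes Cluster counts (defaults 13 and 15).
#' @param window_years Reference-group age window (default 10).
#' @param rule Similarity [link_rule()].
#' @param span LOESS span for index curves.
#' @param out_dir Optional output directory.
#' @return Object of class `bt_result`: list with the cohort, the measure
#'   pipeline stages, meta-measure definition and scores, labeled types,
#'   per-type summary, incidence curves and net change, link matrix,
#'   transition graph, activity/health summaries, and the manifest.
#' @export
run_pipeline <- function(cohort = NULL, config = generator_config(),
                         k_metameasures = 13L, k_bodytypes = 15L,
                         window_years = 10, rule = link_rule(), span = 0.5,
                         activity = NULL, health = NULL, out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  simulated <- is.null(cohort)
  if (simulated) cohort <- stage("simulate", generate_cohort(config))
  else config <- cohort$config %||% config
  p <- cohort$participants

  if (simulated && is.null(activity))
    activity <- stage("simulate", generate_activity(cohort, config))
  if (simulated && is.null(health))
    health <- stage("simulate", generate_health(cohort, config))

  z <- stage("preprocess", {
    sel <- select_measures(cohort$measures)
    z_normalize(height_normalize(sel, p$height))
  })
  indices <- stage("preprocess", cohort_body_indices(cohort))

  metadef <- stage("metameasure",
                   derive_metameasures(z, k = k_metameasures,
                                       seed = config$seed %||% 1L))
  meta <- stage("metameasure", score_metameasures(z, metadef))

  assignment <- stage("bodytype",
                      assign_body_types(meta, k = k_bodytypes,
                                        seed = config$seed %||% 1L))
  types <- stage("bodytype", label_types(assignment, p))
  labels <- stage("bodytype", split_mixed_types(types, p))

  summaries <- stage("bodytype", {
    s <- do.call(rbind, lapply(sort(unique(labels)), function(tp) {
      ids <- names(labels)[labels == tp]
      data.frame(label = tp, n = length(ids),
                 mean_age = mean(p$age[p$id %in% ids]),
                 mean_bmi = mean(indices$bmi[indices$id %in% ids]),
                 mean_wth = mean(indices$wth[indices$id %in% ids]),
                 stringsAsFactors = FALSE)
    }))
    s
  })

  incidence <- stage("aging", incidence_by_age(labels, p))
  net_change <- stage("aging", net_incidence_change(incidence))
  age_corr <- stage("aging", metameasure_age_correlation(meta, p$age, p$sex))

  links <- stage("trajectory", count_similarity_links(meta, labels, rule))
  graph <- stage("trajectory",
                 suppressWarnings(transition_graph(links, summaries)))

  act_summary <- stage("health", if (!is.null(activity))
    activity_by_type(labels, p, activity, window_years) else NULL)
  life <- stage("health", if (!is.null(health))
    lifestyle_summary(labels, health) else NULL)
  pmi <- stage("health", if (!is.null(health)) {
    flag <- health$pmi[match(names(labels), health$id)]
    vapply(split(flag, labels), function(f)
      prevalence(sum(f), length(f)), numeric(1))
  } else NULL)

  manifest <- list(
    seed = config$seed %||% NA_integer_,
    n_participants = nrow(p),
    k_metameasures = k_metameasures, k_bodytypes = k_bodytypes,
    window_years = window_years,
    link_rule = unclass(rule), loess_span = span,
    stage_rows = list(cohort = nrow(p), z_matrix = nrow(z),
                      activity = if (is.null(activity)) 0L else nrow(activity))
  )
  res <- structure(
    list(cohort = cohort, activity = activity, health = health, z = z,
         indices = indices, metadef = metadef, meta = meta, types = types,
         labels = labels, summaries = summaries, incidence = incidence,
         net_change = net_change, age_correlation = age_corr, links = links,
         graph = graph, activity_summary = act_summary,
         lifestyle = life, pmi_by_type = pmi, manifest = manifest),
    class = "bt_result")
  if (!is.null(out_dir)) write_result(res, out_dir)
  res
}

# write the result bundle as plain-text tables + YAML manifest
write_result <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort_tables(res$cohort, out_dir, res$activity, res$health)
  utils::write.csv(data.frame(id = names(res$labels), type = res$labels),
                   file.path(out_dir, "body_types.csv"), row.names = FALSE)
  utils::write.table(res$summaries, file.path(out_dir, "type_summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(as.data.frame(res$links),
                     file.path(out_dir, "link_matrix.tsv"), sep = "\t",
                     quote = FALSE)
  utils::write.table(res$graph, file.path(out_dir, "transitions.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(clusters = res$metadef$clusters),
                   file.path(out_dir, "metameasures.yaml"))
  yaml::write_yaml(res$manifest, file.path(out_dir, "run_manifest.yaml"))
  invisible(out_dir)
}

#' @export
print.bt_result <- function(x, ...) {
  cat("<bt_result> pipeline run:", nrow(x$cohort$participants),
      "participants,", x$metadef$k, "meta-measures,",
      nrow(x$types$summary), "body types\n")
  invisible(x)
}
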