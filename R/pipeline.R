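#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline with its documented
#' default. The configuration round-trips through YAML and its hash is
#' recorded in every artifact so stages can detect mismatched inputs.
#'
#' @param epoch_len Scoring epoch, seconds.
#' @param min_bout Bout-smoothing threshold, minutes.
#' @param max_gap Largest bridged wake gap when building windows, minutes.
#' @param long_short_threshold Long/short window boundary, hours.
#' @param max_nonwear Per-day nonwear validity threshold, hours (strict).
#' @param min_consecutive_days Minimum run of valid days to analyse.
#' @param max_days Cap on the analysed span, days.
#' @param bin_len Wake binning for the rhythm indexes, minutes.
#' @param period_range Candidate period range, hours.
#' @param alpha Periodogram significance level.
#' @param mu Van der Pol damping for phase fitting.
#' @param phase_grid_min Phase-shift grid, minutes.
#' @param midawake_split Long/short midawake boundary, minutes.
#' @param embedding Method for [embed_indexes].
#' @param n_neighbors,min_dist UMAP parameters.
#' @param eps DBSCAN radius (`NULL` = per-node kNN heuristic).
#' @param min_child_size Minimum accepted child size / DBSCAN min_samples.
#' @param max_depth Divisive clustering depth.
#' @param ward_groups Ward regrouping target per first-layer cluster.
#' @param outlier_pct Outlier tail percentile.
#' @param outlier_indexes Index names for the outlier branch.
#' @param seed Master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(epoch_len = 30,
                            min_bout = 10,
                            max_gap = 60,
                            long_short_threshold = 3.75,
                            max_nonwear = 5,
                            min_consecutive_days = 4,
                            max_days = 7,
                            bin_len = 10,
                            period_range = c(5, 35),
                            alpha = 0.01,
                            mu = 1.0,
                            phase_grid_min = 1,
                            midawake_split = 60,
                            embedding = "umap",
                            n_neighbors = 50,
                            min_dist = 0.0,
                            eps = NULL,
                            min_child_size = 20,
                            max_depth = 3,
                            ward_groups = 2,
                            outlier_pct = 2.28,
                            outlier_indexes = c("wt_long_mn", "st_long_sd",
                                                "st_short_mn",
                                                "sleep_percentage_mn",
                                                "phase_mn", "period"),
                            seed = 1) {
  stopifnot(
    epoch_len > 0, 86400 %% epoch_len == 0,
    min_bout > 0, max_gap >= 0, long_short_threshold > 0,
    max_nonwear > 0, max_nonwear <= 24,
    min_consecutive_days >= 1, max_days >= min_consecutive_days,
    period_range[1] >= 5 / 60, period_range[2] <= 48,
    alpha > 0, alpha < 1, mu > 0,
    outlier_pct > 0, outlier_pct < 50,
    min_child_size >= 2, max_depth >= 1
  )
  structure(as.list(environment()), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname pipeline_config
#' @export
config_hash <- function(config) {
  rlang::hash(unclass(config))
}

#' Extract the 21 sleep indexes for one subject
#'
#' Runs the per-subject half of the pipeline: smoothing, noon-day
#' segmentation, valid-span selection, sleep windows, daily metrics, rhythm
#' indexes, and the final 21-value vector.
#'
#' @param series The subject's [sw_series].
#' @param config A [pipeline_config].
#' @return A one-row tibble of the 21 indexes plus `n_valid_days`, or
#'   `NULL` when no valid span exists.
#' @export
extract_sleep_indexes <- function(series, config = pipeline_config()) {
  sm <- smooth_series(series, min_bout = config$min_bout)
  days <- segment_noon_days(sm, max_nonwear = config$max_nonwear)
  span <- select_valid_span(days, max_nonwear = config$max_nonwear,
                            min_consecutive_days = config$min_consecutive_days,
                            max_days = config$max_days)
  if (length(span) == 0) return(NULL)
  sel_days <- days[days$day_index %in% span, ]
  sub <- window_slice(sm, min(sel_days$day_start), max(sel_days$day_end))
  sub_days <- segment_noon_days(sub, max_nonwear = config$max_nonwear)
  windows <- label_windows(build_windows(sub, max_gap = config$max_gap),
                           threshold = config$long_short_threshold)
  daily <- daily_metrics(sub_days, windows, sub,
                         midawake_split = config$midawake_split)
  rhythm <- rhythm_summary(
    sub, sub_days, bin_len = config$bin_len,
    p_min = config$period_range[1], p_max = config$period_range[2],
    alpha = config$alpha, mu = config$mu, grid_min = config$phase_grid_min
  )
  vec <- compute_index_vector(daily, rhythm, total_windows = nrow(windows))
  vec$n_valid_days <- nrow(sub_days)
  vec
}

#' Index an entire cohort
#'
#' @param cohort Cohort tibble from [generate_cohort] (columns
#'   `subject_id`, `series`, optionally `archetype`).
#' @param config A [pipeline_config].
#' @return Index table: one row per subject with a valid span.
#' @export
index_cohort <- function(cohort, config = pipeline_config()) {
  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    v <- extract_sleep_indexes(cohort$series[[i]], config)
    if (is.null(v)) return(NULL)
    v$subject_id <- cohort$subject_id[i]
    if ("archetype" %in% names(cohort)) v$archetype <- cohort$archetype[i]
    v
  }) |> purrr::compact()
  if (length(rows) == 0) {
    return(tibble::tibble(subject_id = character()))
  }
  out <- purrr::list_rbind(rows)
  dplyr::relocate(out, "subject_id")
}

#' Run the full landscape pipeline on a cohort
#'
#' Simulation (optional) -> per-subject indexes -> z-scoring -> divisive
#' clustering -> Ward regrouping -> outlier branch -> profiles, with a
#' machine-readable run report.
#'
#' @param config A [pipeline_config].
#' @param cohort A cohort tibble ([generate_cohort]); if `NULL`,
#'   `simulate` must give `list(specs = , n_days = )` to generate one.
#' @param simulate Simulation spec used when `cohort` is NULL.
#' @param out_dir Optional directory; when given, artifacts (index table,
#'   labels, profiles CSV, tree and report JSON) are written there.
#' @param run_outlier_branch Whether to run the percentile outlier
#'   re-clustering.
#' @return A list of class `sleepscape_run`: `index_table`, `z`, `tree`,
#'   `labels` (tibble with final Ward-regrouped labels), `profiles`,
#'   `outliers` (mask + labels or NULL), `report`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL,
                         simulate = NULL, out_dir = NULL,
                         run_outlier_branch = TRUE) {
  t0 <- Sys.time()
  if (is.null(cohort)) {
    if (is.null(simulate)) stop("either cohort or simulate must be given")
    cohort <- generate_cohort(simulate$specs,
                              n_days = simulate$n_days %||% 6,
                              seed = config$seed,
                              epoch_len = config$epoch_len)
  }
  n_in <- nrow(cohort)
  index_table <- index_cohort(cohort, config)
  n_valid <- nrow(index_table)
  report <- list(subjects_in = n_in, subjects_valid = n_valid,
                 config_hash = config_hash(config), seed = config$seed)

  if (n_valid < 2 * config$min_child_size) {
    report$status <- "stopped_after_indexing"
    report$subjects_clustered <- 0L
    report$wall_time_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    res <- structure(
      list(index_table = index_table, z = NULL, tree = NULL, labels = NULL,
           profiles = NULL, outliers = NULL, report = report),
      class = "sleepscape_run"
    )
    if (!is.null(out_dir)) write_run(res, out_dir, config)
    return(res)
  }

  idx_only <- index_table[, c("subject_id", sleep_index_names())]
  z <- suppressWarnings(zscore_indexes(idx_only))
  tree <- divisive_cluster(
    idx_only, max_depth = config$max_depth,
    min_child_size = config$min_child_size, seed = config$seed,
    method = config$embedding, eps = config$eps,
    n_neighbors = config$n_neighbors, min_dist = config$min_dist
  )
  regrouped <- ward_regroup(tree, z, n_groups = config$ward_groups)
  labels <- dplyr::left_join(
    tibble::tibble(subject_id = idx_only$subject_id), regrouped,
    by = "subject_id"
  )
  labels$label[is.na(labels$label)] <- "noise"
  profiles <- cluster_profiles(labels$label, z)

  outliers <- NULL
  if (run_outlier_branch) {
    mask <- select_outliers(idx_only, indexes = config$outlier_indexes,
                            pct = config$outlier_pct)
    if (sum(mask) >= config$min_child_size) {
      olab <- outlier_cluster(idx_only[mask, ], seed = config$seed,
                              method = config$embedding, eps = config$eps,
                              min_samples = config$min_child_size,
                              n_neighbors = config$n_neighbors,
                              min_dist = config$min_dist)
      outliers <- list(mask = mask,
                       labels = tibble::tibble(
                         subject_id = idx_only$subject_id[mask],
                         label = olab))
    }
  }

  report$subjects_clustered <- sum(labels$label != "noise")
  report$n_noise <- sum(labels$label == "noise")
  report$n_clusters <- nrow(profiles)
  report$status <- "completed"
  report$wall_time_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  res <- structure(
    list(index_table = index_table, z = z, tree = tree, labels = labels,
         profiles = profiles, outliers = outliers, report = report),
    class = "sleepscape_run"
  )
  if (!is.null(out_dir)) write_run(res, out_dir, config)
  res
}

write_run <- function(res, out_dir, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash_line <- paste0("# config_hash=", config_hash(config))
  write_hashed_csv <- function(df, path) {
    writeLines(hash_line, path)
    suppressWarnings(
      utils::write.table(df, path, sep = ",", row.names = FALSE,
                         col.names = TRUE, append = TRUE, qmethod = "double")
    )
  }
  write_hashed_csv(res$index_table, file.path(out_dir, "indexes.csv"))
  if (!is.null(res$labels)) {
    write_hashed_csv(res$labels, file.path(out_dir, "labels.csv"))
    write_hashed_csv(res$profiles, file.path(out_dir, "profiles.csv"))
    jsonlite::write_json(tree_to_list(res$tree$root),
                         file.path(out_dir, "tree.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(res$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

tree_to_list <- function(node) {
  list(
    depth = node$depth,
    size = length(node$members),
    members = node$members,
    noise = node$noise,
    leaf_label = if (is.na(node$leaf_label)) NULL else node$leaf_label,
    children = purrr::map(node$children, tree_to_list)
  )
}

#' Read a pipeline artifact CSV, checking the config hash
#'
#' @param path CSV written by [run_pipeline].
#' @param config Optional `pipeline_config`; a hash mismatch warns.
#' @return Tibble.
#' @export
read_artifact <- function(path, config = NULL) {
  first <- readLines(path, n = 1)
  if (!is.null(config) && startsWith(first, "# config_hash=")) {
    h <- sub("# config_hash=", "", first)
    if (h != config_hash(config)) {
      warning("config hash mismatch: artifact written under a different ",
              "configuration")
    }
  }
  tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
}
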