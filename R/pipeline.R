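# End-to-end orchestration: simulate (or load) -> preprocess -> coherence ->
# graph -> resilience -> stats grid, with CSV artifacts and a run manifest.

#' Per-subject derived measures
#'
#' Computes, for every band: the three connectivity summaries, the three
#' topology measures, targeted-attack relative efficiencies for
#' `k = 1..k_max`, random-failure means, and the top-3 hub normalized
#' degrees. Column names are `measure.band`.
#'
#' @param recording A [segmented_recording()] (already preprocessed).
#' @param montage An `electrode_montage`.
#' @param bands List of [frequency_band()].
#' @param welch A [welch_config()].
#' @param k_max Maximum removals for the resilience profiles.
#' @param rf_replicates Random-failure replicates.
#' @param seed Seed for the random-failure draws.
#' @return Named numeric vector.
#' @export
subject_measures <- function(recording, montage = build_standard_montage(),
                             bands = frequency_bands(),
                             welch = welch_config(), k_max = 5,
                             rf_replicates = 200, seed = 1) {
  mats <- band_coherence_matrices(recording, bands, welch)
  out <- numeric(0)
  for (bc in mats) {
    b <- bc$band$name
    g <- build_graph(bc)
    s <- connectivity_summary(bc, montage)
    gm <- graph_metrics(g)
    ta <- targeted_attack(g, k_max)
    rf <- random_failure(g, k_max, rf_replicates, seed = seed)
    hub <- hub_normalized_degree(g, 1:3)
    v <- c(mean_coherence = s$mean_coherence,
           inter_intra_ratio = s$inter_intra_ratio,
           long_short_ratio = s$long_short_ratio,
           path_length = gm$path_length,
           clustering = gm$clustering,
           efficiency = gm$efficiency,
           stats::setNames(ta$relative_efficiency[ta$k > 0],
                           paste0("ta_k", ta$k[ta$k > 0])),
           stats::setNames(rf$relative_efficiency[rf$k > 0],
                           paste0("rf_k", rf$k[rf$k > 0])),
           stats::setNames(hub$normalized_degree,
                           paste0("hub", hub$rank)))
    names(v) <- paste(names(v), b, sep = ".")
    out <- c(out, v)
  }
  out
}

#' Cohort measure table
#'
#' Applies [subject_measures()] to every recording of a cohort and binds the
#' result to the metadata, yielding the one-row-per-subject table consumed
#' by the ANCOVA. Subject-level failures (e.g. insufficient data) are
#' excluded with a reason, reported in `attr(, "exclusions")`.
#'
#' @param recordings List of [segmented_recording()].
#' @param metadata Data frame with one row per recording (`subject_id`,
#'   `ASD`, `TSC`, `age`, ...).
#' @param preprocess Either `NULL` (use recordings as-is) or a function
#'   applied to each recording before measurement.
#' @inheritParams subject_measures
#' @return Data frame (metadata columns + measure columns).
#' @export
cohort_measures <- function(recordings, metadata,
                            montage = build_standard_montage(),
                            bands = frequency_bands(),
                            welch = welch_config(), k_max = 5,
                            rf_replicates = 200, seed = 1,
                            preprocess = NULL) {
  stopifnot(length(recordings) == nrow(metadata))
  rows <- list(); exclusions <- list()
  for (i in seq_along(recordings)) {
    res <- tryCatch({
      rec <- recordings[[i]]
      if (!is.null(preprocess)) rec <- preprocess(rec)
      subject_measures(rec, montage, bands, welch, k_max, rf_replicates,
                       seed = derive_seed(seed, 100000 + i))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      exclusions[[length(exclusions) + 1]] <- data.frame(
        subject_id = metadata$subject_id[i], reason = conditionMessage(res),
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1]] <- cbind(metadata[i, , drop = FALSE],
                                        as.data.frame(t(res)))
    }
  }
  if (length(rows) == 0) stop("no subject survived preprocessing")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "exclusions") <-
    if (length(exclusions)) do.call(rbind, exclusions) else
      data.frame(subject_id = character(0), reason = character(0))
  out
}

#' Pipeline run configuration
#'
#' Exactly one input mode: a synthetic cohort specification, or a directory
#' of EDF files plus a metadata CSV (columns `subject_id`, `ASD`, `TSC`,
#' `age`; EDFs named `<subject_id>.edf` with optional
#' `<subject_id>_segments.csv` boundary sidecars).
#'
#' @param synthetic_spec A [synthetic_cohort_spec()], or `NULL`.
#' @param edf_dir Directory of EDF inputs, or `NULL`.
#' @param metadata Metadata CSV path (EDF mode).
#' @param bands List of [frequency_band()].
#' @param welch A [welch_config()].
#' @param preprocess A [preprocess_config()].
#' @param apply_filters Run the FIR notch/band-pass chain (the average
#'   reference is always applied before coherence).
#' @param k_max,rf_replicates Resilience settings.
#' @param seed Integer seed for all randomness in the run.
#' @param out_dir Output directory for CSV artifacts and the manifest
#'   (`NULL` = in-memory only).
#' @return A list of class `run_config`.
#' @export
run_config <- function(synthetic_spec = NULL, edf_dir = NULL,
                       metadata = NULL, bands = frequency_bands(),
                       welch = welch_config(),
                       preprocess = preprocess_config(),
                       apply_filters = TRUE, k_max = 5,
                       rf_replicates = 200, seed = 1, out_dir = NULL) {
  if (is.null(synthetic_spec) == is.null(edf_dir))
    stop("exactly one input mode: synthetic_spec or edf_dir")
  structure(list(synthetic_spec = synthetic_spec, edf_dir = edf_dir,
                 metadata = metadata, bands = bands, welch = welch,
                 preprocess = preprocess, apply_filters = apply_filters,
                 k_max = k_max, rf_replicates = rf_replicates,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Recognized top-level keys mirror the [run_config()] arguments; nested
#' maps `synthetic_spec`, `welch`, `preprocess` and a `bands` list of
#' `{name, low, high}` entries are converted to their typed configs.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$synthetic_spec))
    args$synthetic_spec <- do.call(synthetic_cohort_spec, y$synthetic_spec)
  for (k in c("edf_dir", "metadata", "apply_filters", "k_max",
              "rf_replicates", "seed", "out_dir"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  if (!is.null(y$welch)) args$welch <- do.call(welch_config, y$welch)
  if (!is.null(y$preprocess))
    args$preprocess <- do.call(preprocess_config, y$preprocess)
  if (!is.null(y$bands))
    args$bands <- lapply(y$bands, function(b)
      frequency_band(b$name, b$low, b$high))
  do.call(run_config, args)
}

# Tiny FNV-1a hash of the serialized configuration, for the run manifest.
config_hash <- function(config) {
  bytes <- as.integer(serialize(unclass(config), NULL))
  h <- 2166136261
  for (b in bytes) h <- ((bitwXor(as.integer(h %% 2147483647), b)) *
                           16777619) %% 4294967296
  sprintf("%08x", as.integer(h %% 2147483647))
}

acquire_cohort <- function(config) {
  if (!is.null(config$synthetic_spec)) {
    return(generate_cohort(config$synthetic_spec))
  }
  meta <- utils::read.csv(config$metadata, stringsAsFactors = FALSE)
  montage <- build_standard_montage()
  recordings <- lapply(meta$subject_id, function(id) {
    edf <- file.path(config$edf_dir, paste0(id, ".edf"))
    sidecar <- file.path(config$edf_dir, paste0(id, "_segments.csv"))
    rec <- load_recording(edf, montage)
    bounds <- if (file.exists(sidecar))
      utils::read.csv(sidecar) else NULL
    list(record = rec, boundaries = bounds)
  })
  structure(list(recordings = recordings, metadata = meta,
                 from_edf = TRUE), class = "eeg_cohort")
}

preprocess_segmented <- function(rec, config) {
  if (config$apply_filters)
    rec$segments <- lapply(rec$segments, function(s) {
      out <- filter_record(s, config$preprocess, fs = rec$sampling_rate)
      colnames(out) <- colnames(s)
      out
    })
  average_reference(rec)
}

GRID_MEASURES <- c("mean_coherence", "inter_intra_ratio", "long_short_ratio",
                   "clustering", "path_length", "efficiency",
                   paste0("ta_k", 1:5))

#' Run the full analysis pipeline
#'
#' Simulate (or load) a cohort, preprocess every subject, compute the
#' per-band coherence matrices, connectivity summaries, graph topology,
#' resilience and hub measures, assemble the cohort table, and fit the
#' two-way ANCOVA grid. With `out_dir` set, writes `cohort_measures.csv`,
#' `ancova_grid.csv`, `pvalue_table.csv`, `demographics.csv`,
#' `exclusions.csv` and `manifest.json`. Identical configuration and seed
#' give identical outputs.
#'
#' @param config A [run_config()].
#' @return List (invisible when writing to disk): `table` (cohort measure
#'   table), `grid` (long ANCOVA grid), `pvalues` (Table-style p-value
#'   grid), `demographics`, `exclusions`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  montage <- build_standard_montage()
  cohort <- acquire_cohort(config)

  if (isTRUE(cohort$from_edf)) {
    recordings <- lapply(cohort$recordings, function(it) {
      preprocess_subject(it$record, montage, it$boundaries,
                         config$preprocess, config$welch)
    })
    meta <- cohort$metadata
    table <- cohort_measures(recordings, meta, montage, config$bands,
                             config$welch, config$k_max,
                             config$rf_replicates, config$seed)
  } else {
    table <- cohort_measures(cohort$recordings, cohort$metadata, montage,
                             config$bands, config$welch, config$k_max,
                             config$rf_replicates, config$seed,
                             preprocess = function(r)
                               preprocess_segmented(r, config))
  }

  # require at least 2 survivors per populated design cell
  cells <- interaction(table$ASD, table$TSC, drop = TRUE)
  if (any(table(cells) < 2))
    stop("fewer than 2 subjects survived in a design subgroup")

  band_names <- vapply(config$bands, function(b) b$name, character(1))
  measures <- intersect(GRID_MEASURES,
                        unique(sub("\\..*$", "", setdiff(names(table),
                          c("subject_id", "ASD", "TSC", "age", "sex", "ACC")))))
  grid <- ancova_grid(table, measures, band_names)
  pvals <- grid_pvalue_table(grid)
  demo <- demographic_tests(table)
  manifest <- list(
    package = "cohgraph",
    version = as.character(utils::packageVersion("cohgraph")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    config_hash = config_hash(config),
    n_subjects = nrow(table),
    bands = band_names)

  exclusions <- attr(table, "exclusions")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(df, f) utils::write.csv(
      df, file.path(config$out_dir, f), row.names = FALSE)
    w(table, "cohort_measures.csv")
    w(grid, "ancova_grid.csv")
    w(pvals, "pvalue_table.csv")
    if (!is.null(demo)) w(demo, "demographics.csv")
    w(exclusions, "exclusions.csv")
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(list(table = table, grid = grid, pvalues = pvals,
                 demographics = demo, exclusions = exclusions,
                 manifest = manifest))
}
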