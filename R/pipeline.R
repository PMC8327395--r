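#' Pipeline run configuration
#'
#' One declarative object driving the whole analysis: either file inputs
#' (`gaze_path` + `annotation_path`) or simulation settings (`simulate =
#' TRUE` with per-class phase counts), plus the sub-configurations of every
#' stage and a master seed from which per-stage seeds are derived
#' deterministically. Serializable to/from JSON via [write_run_config()] /
#' [read_run_config()].
#'
#' @param simulate generate the input recording (`TRUE`) or read it from
#'   files (`FALSE`).
#' @param gaze_path,annotation_path input files (file mode).
#' @param n_mnl,n_non,n_mnl_test,n_non_test phase counts (simulate mode);
#'   the test counts mirror the held-out validation split.
#' @param geometry a [screen_geometry()].
#' @param ivt an [ivt_config()].
#' @param gan a [gan_config()].
#' @param lstm an [lstm_config()].
#' @param preset_mnl,preset_non [class_preset()]s (simulate mode).
#' @param synth_sizes feeding-strategy synthetic sizes per class.
#' @param seed master seed.
#' @param outdir output directory (`NULL`: nothing written).
#' @return An object of class `run_config`.
#' @export
run_config <- function(simulate = TRUE,
                       gaze_path = NULL, annotation_path = NULL,
                       n_mnl = 51, n_non = 77,
                       n_mnl_test = 17, n_non_test = 44,
                       geometry = screen_geometry(),
                       ivt = ivt_config(),
                       gan = gan_config(),
                       lstm = lstm_config(),
                       preset_mnl = mnl_preset(),
                       preset_non = non_mnl_preset(),
                       synth_sizes = c(0, 200, 1000, 1600, 2000),
                       seed = 1,
                       outdir = NULL) {
  if (!simulate && (is.null(gaze_path) || is.null(annotation_path))) {
    stop_config("file mode needs both gaze_path and annotation_path")
  }
  if (simulate && (!is.null(gaze_path) || !is.null(annotation_path))) {
    stop_config("choose exactly one input mode: simulate or files")
  }
  structure(as.list(environment()), class = "run_config")
}

flatten_config <- function(cfg) {
  list(
    simulate = cfg$simulate, gaze_path = cfg$gaze_path,
    annotation_path = cfg$annotation_path,
    n_mnl = cfg$n_mnl, n_non = cfg$n_non,
    n_mnl_test = cfg$n_mnl_test, n_non_test = cfg$n_non_test,
    geometry = unclass(cfg$geometry), ivt = unclass(cfg$ivt),
    gan = unclass(cfg$gan), lstm = unclass(cfg$lstm),
    preset_mnl = unclass(cfg$preset_mnl)[!vapply(cfg$preset_mnl, is.null, TRUE)],
    preset_non = unclass(cfg$preset_non)[!vapply(cfg$preset_non, is.null, TRUE)],
    synth_sizes = cfg$synth_sizes, seed = cfg$seed, outdir = cfg$outdir
  )
}

config_hash <- function(cfg) {
  # fingerprint of the canonical JSON form so every artifact names the
  # config that produced it and the hash survives serialization round trips
  # (no cryptographic intent)
  s <- as.character(jsonlite::toJSON(flatten_config(cfg), auto_unbox = TRUE,
                                     digits = NA, null = "null"))
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% .Machine$integer.max)
}

#' Serialize / restore a run configuration as JSON
#'
#' @param cfg a [run_config()].
#' @param path JSON file path.
#' @return `path` invisibly; the reader returns a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  jsonlite::write_json(flatten_config(cfg), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(
    simulate = x$simulate,
    gaze_path = x$gaze_path, annotation_path = x$annotation_path,
    n_mnl = x$n_mnl, n_non = x$n_non,
    n_mnl_test = x$n_mnl_test, n_non_test = x$n_non_test,
    geometry = do.call(screen_geometry, as.list(x$geometry)),
    ivt = do.call(ivt_config, as.list(x$ivt)),
    gan = do.call(gan_config, as.list(x$gan)),
    lstm = do.call(lstm_config, as.list(x$lstm)),
    preset_mnl = do.call(class_preset, as.list(x$preset_mnl)),
    preset_non = do.call(class_preset, as.list(x$preset_non)),
    synth_sizes = x$synth_sizes, seed = x$seed, outdir = x$outdir
  )
}

pipeline_log <- function(stage, fmt, ...) {
  message(sprintf("[gazenav:%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Simulate (or ingest) a recording, detect gaze events, extract per-phase
#' metric panels and classifier features, compare the groups and select
#' features, train per-class adversarial augmenters with an overlap check,
#' run the feeding-strategy experiment and evaluate on a held-out split.
#' Every stage derives its seed deterministically from the master seed and
#' logs its input/output sizes; when `cfg$outdir` is set, each stage writes
#' its CSV artifact there (suffixed with the config fingerprint).
#'
#' @param cfg a [run_config()].
#' @return A list of class `run_report`: `comparison`, `selected_features`,
#'   `features_train`, `features_test`, `overlap`, `feeding`, `config_hash`,
#'   `seeds`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  hash <- config_hash(cfg)
  art <- function(name) {
    if (is.null(cfg$outdir)) return(NULL)
    if (!dir.exists(cfg$outdir)) dir.create(cfg$outdir, recursive = TRUE)
    file.path(cfg$outdir, sprintf("%s_%s.csv", name, hash))
  }
  # --- stage: input
  if (cfg$simulate) {
    train_set <- generate_dataset(
      cfg$n_mnl, cfg$n_non, cfg$preset_mnl, cfg$preset_non,
      seed = derive_seed(cfg$seed, "simulate_train"), geometry = cfg$geometry
    )
    test_set <- generate_dataset(
      cfg$n_mnl_test, cfg$n_non_test, cfg$preset_mnl, cfg$preset_non,
      seed = derive_seed(cfg$seed, "simulate_test"), geometry = cfg$geometry
    )
    inputs <- list(
      list(recording = train_set$recording, annotations = train_set$annotations),
      list(recording = test_set$recording, annotations = test_set$annotations)
    )
  } else {
    rec <- read_gaze_table(cfg$gaze_path, geometry = cfg$geometry)
    ann <- read_phase_annotations(cfg$annotation_path)
    inputs <- list(list(recording = rec, annotations = ann))
  }
  pipeline_log("input", "%d recording(s), %d total samples",
               length(inputs),
               sum(vapply(inputs, function(i) nrow(i$recording$samples), 0)))
  # --- stage: events + features
  sets <- purrr::map(inputs, function(inp) {
    ev <- detect_events(inp$recording, cfg$ivt)
    list(
      events = ev,
      metrics = phase_metrics(inp$recording, inp$annotations, events = ev, cfg = cfg$ivt),
      features = mutate(
        phase_features(inp$recording, inp$annotations, events = ev, cfg = cfg$ivt),
        origin = "real"
      )
    )
  })
  # distinct phase ids across the independent splits (leakage bookkeeping)
  sets <- purrr::imap(sets, function(s, i) {
    pre <- if (i == 1) "train" else "test"
    s$features <- mutate(s$features, phase_id = paste0(pre, "_", .data$phase_id))
    s
  })
  pipeline_log("events", "%s events detected",
               paste(vapply(sets, function(s) nrow(s$events), 0), collapse = " + "))
  features_train <- sets[[1]]$features
  features_test <- if (length(sets) > 1) sets[[2]]$features else NULL
  if (!is.null(art("features_train"))) {
    write_feature_table(features_train, art("features_train"))
    if (!is.null(features_test)) write_feature_table(features_test, art("features_test"))
  }
  # --- stage: group statistics + feature selection
  comparison <- build_comparison_tables(sets[[1]]$metrics)
  selected <- select_features(comparison)
  pipeline_log("compare", "%d measures, %d significant, %d selected",
               nrow(comparison), sum(comparison$p_value < 0.05), length(selected))
  if (!is.null(art("comparison"))) {
    readr::write_csv(tidy(comparison), art("comparison"), progress = FALSE)
  }
  if (is.null(features_test)) {
    return(structure(
      list(
        comparison = comparison, selected_features = selected,
        features_train = features_train, features_test = NULL,
        overlap = NULL, feeding = NULL, config_hash = hash
      ),
      class = "run_report"
    ))
  }
  # --- stage: augmentation + overlap check
  gan_mnl <- train_dcgan(
    filter(features_train, .data$label == "MNL"),
    utils::modifyList(cfg$gan, list(seed = derive_seed(cfg$seed, "gan_mnl")))
  )
  gan_non <- train_dcgan(
    filter(features_train, .data$label == "non-MNL"),
    utils::modifyList(cfg$gan, list(seed = derive_seed(cfg$seed, "gan_non")))
  )
  overlap <- purrr::map(
    list(MNL = gan_mnl, `non-MNL` = gan_non),
    function(g) {
      embedding_overlap(
        filter(features_train, .data$label == g$label),
        sample_synthetic(g, 200, seed = derive_seed(cfg$seed, paste0("overlap_", g$label))),
        seed = derive_seed(cfg$seed, "embed")
      )
    }
  )
  pipeline_log("augment", "overlap separability MNL %.3f, non-MNL %.3f",
               overlap$MNL$separability, overlap$`non-MNL`$separability)
  # --- stage: feeding experiment
  feeding <- feeding_experiment(
    features_train, features_test,
    gan_mnl = gan_mnl, gan_non = gan_non,
    synth_sizes = cfg$synth_sizes,
    lstm_cfg = cfg$lstm, seed = derive_seed(cfg$seed, "feeding")
  )
  pipeline_log("classify", "best accuracy %.2f%% (%s)",
               max(feeding$accuracy), feeding$strategy[which.max(feeding$accuracy)])
  if (!is.null(art("feeding"))) {
    readr::write_csv(select(feeding, -"metrics"), art("feeding"), progress = FALSE)
    roc <- bind_rows(lapply(seq_len(nrow(feeding)), function(i) {
      mutate(feeding$metrics[[i]]$roc, strategy = feeding$strategy[i])
    }))
    readr::write_csv(roc, art("roc"), progress = FALSE)
  }
  structure(
    list(
      comparison = comparison, selected_features = selected,
      features_train = features_train, features_test = features_test,
      overlap = overlap, feeding = feeding, config_hash = hash
    ),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> config %s\n", x$config_hash))
  cat(sprintf("  %d measures compared, %d features selected\n",
              nrow(x$comparison), length(x$selected_features)))
  if (!is.null(x$feeding)) {
    best <- which.max(x$feeding$accuracy)
    cat(sprintf("  best strategy %s: accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%\n",
                x$feeding$strategy[best], x$feeding$accuracy[best],
                x$feeding$sensitivity[best], x$feeding$specificity[best]))
  }
  invisible(x)
}
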