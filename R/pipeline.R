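#' Cross-patient trajectory map
#'
#' Per-minute cross-patient mean and sample SD of the raw (unnormalized)
#' signals, respecting validity masks; defined only where at least 2
#' patients are valid.
#'
#' @param records list of [patient_record()]s (>= 2).
#' @param signals base signals to map (default all).
#' @return Object of class `trajectory_map`: data.frame with columns
#'   `signal`, `minute`, `mean`, `sd`, `n`.
#' @export
trajectory_map <- function(records, signals = SPM_SIGNALS) {
  if (length(records) < 2L) stop_data("need at least 2 patients")
  tensor <- build_tensor(records)
  out <- lapply(signals, function(sig) {
    j <- match(sig, tensor$signal_labels)
    X <- tensor$data[, j, , drop = TRUE]
    V <- tensor$valid[, j, , drop = TRUE]
    X[!V] <- NA_real_
    n <- colSums(V)
    m <- colMeans(X, na.rm = TRUE)
    s <- sqrt(colSums(sweep(X, 2L, m)^2, na.rm = TRUE) / pmax(n - 1L, 1L))
    m[n < 2L] <- NA_real_
    s[n < 2L] <- NA_real_
    data.frame(signal = sig, minute = tensor$minutes, mean = m, sd = s,
               n = n, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, out), class = c("trajectory_map", "data.frame"))
}

#' Fit the full monitoring model on a training cohort
#'
#' Runs the model-building half of the framework: tensor assembly, lag
#' augmentation, batch-wise normalization, variable-wise unfolding, PCA
#' and SFA fits, and the training SPE values needed for the windowed SPE
#' limit.  Excluded records (sensor dropout above the exclusion threshold)
#' are refused unless `config$exclusion$override` is set.
#'
#' @param train_records list of [patient_record()]s (>= 2).
#' @param config configuration from [spm_config()].
#' @return Object of class `monitoring_model`: `normalization`, `pca`,
#'   `sfa`, `spe_train` (training patients x minutes), `config`,
#'   `train_ids`, `K`.
#' @export
fit_monitoring_model <- function(train_records, config = spm_config()) {
  if (length(train_records) < 2L)
    stop_data("need at least 2 training patients")
  excl <- vapply(train_records, `[[`, TRUE, "excluded")
  if (any(excl)) {
    ids <- vapply(train_records[excl], `[[`, "", "patient_id")
    if (!isTRUE(config$exclusion$override))
      stop_data("excluded patient(s) in training set: %s (set exclusion$override to proceed)",
                paste(ids, collapse = ", "))
    message("proceeding with excluded patient(s): ",
            paste(ids, collapse = ", "))
  }
  tensor <- lag_augment(build_tensor(train_records), config$lags$n)
  norm <- fit_normalization(tensor,
                            spo2_mu = config$normalization$spo2_mu,
                            spo2_sigma = config$normalization$spo2_sigma,
                            sigma_floor_rel = config$normalization$sigma_floor_rel)
  z <- apply_normalization(tensor, norm)
  uf <- variable_wise_unfold(z)
  pca <- fit_pca(uf, c = config$pca$c, coverage = config$pca$coverage)
  sfa <- fit_sfa(uf, pca = pca, d = config$sfa$d %||% pca$c)
  S <- pca_scores(uf$X, pca)
  J <- ncol(S)
  resid_cols <- (pca$c + 1L):J
  spe_rows <- rowSums(S[, resid_cols, drop = FALSE]^2)
  spe_train <- fold_statistic(spe_rows, uf$row_index,
                              patient_ids = tensor$patient_ids, K = uf$K)
  structure(list(normalization = norm, pca = pca, sfa = sfa,
                 spe_train = spe_train, config = config,
                 train_ids = tensor$patient_ids, K = uf$K),
            class = "monitoring_model")
}

#' Monitor one patient against a fitted model
#'
#' Normalizes and scores the patient's traces with the training-cohort
#' models and produces the four control charts (PCA T2, PCA SPE, SFA slow
#' and fast block T2).  Minutes with any invalid (lagged) entry are chart
#' gaps.  Dropout spark intervals (maximal invalid runs per base signal,
#' intersected over signals) are attached for display.
#'
#' @param record a [patient_record()] on the model's grid.
#' @param model a [fit_monitoring_model()] result.
#' @return Object of class `monitoring_result`: `patient_id`, `charts`
#'   (named list `PCA_T2`, `PCA_SPE`, `SFA_T2D`, `SFA_T2E`),
#'   `dropout_sparks`, `valid_minutes`.
#' @export
monitor_patient <- function(record, model) {
  stopifnot(inherits(model, "monitoring_model"))
  cfg <- model$config
  if (record$excluded && !isTRUE(cfg$exclusion$override))
    stop_data("patient %s is excluded (set exclusion$override to monitor anyway)",
              record$patient_id)
  tensor <- lag_augment(build_tensor(list(record)), cfg$lags$n)
  if (dim(tensor$data)[3L] != model$K)
    stop_contract("record grid (%d) does not match model grid (%d)",
                  dim(tensor$data)[3L], model$K)
  z <- apply_normalization(tensor, model$normalization)
  uf <- variable_wise_unfold(z)
  K <- model$K
  J <- nrow(model$pca$U)
  alpha <- cfg$charts$alpha
  c <- model$pca$c; d <- model$sfa$d
  if (nrow(uf$X)) {
    Sp <- pca_scores(uf$X, model$pca)
    Ss <- sfa_scores(uf$X, model$sfa)
  } else {
    Sp <- Ss <- matrix(0, 0L, J)
  }
  fold_scores <- function(S) {
    out <- matrix(NA_real_, K, J)
    if (nrow(S)) out[uf$row_index$minute + 1L, ] <- S
    out
  }
  Spk <- fold_scores(Sp); Ssk <- fold_scores(Ss)
  minutes <- 0:(K - 1L)
  charts <- list(
    PCA_T2 = t2_chart(Spk, c = c, alpha = alpha, minutes = minutes),
    PCA_SPE = spe_chart(Spk[, (c + 1L):J, drop = FALSE], model$spe_train,
                        window = cfg$spe$window, alpha = alpha,
                        minutes = minutes))
  sf <- sfa_t2_charts(Ssk, d = d, alpha = alpha, minutes = minutes)
  charts$SFA_T2D <- sf$T2D
  charts$SFA_T2E <- sf$T2E
  base_valid <- Reduce(`&`, lapply(record$traces, `[[`, "valid"))
  r <- rle(!base_valid)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  sparks <- data.frame(start = starts[r$values] - 1L, end = ends[r$values])
  structure(list(patient_id = record$patient_id, charts = charts,
                 dropout_sparks = sparks,
                 valid_minutes = minutes[!is.na(charts$PCA_T2$statistic)]),
            class = "monitoring_result")
}

#' Leave-one-out monitoring over a cohort
#'
#' For each patient, the normalization, latent models and control limits
#' are fitted on the other patients only, and the held-out patient is
#' scored against that fold's models — so no patient's data influences the
#' charts used for their own assessment.
#'
#' @param records list of [patient_record()]s (>= 3).
#' @param config configuration from [spm_config()].
#' @param annotations optional annotation table from [read_annotations()].
#' @param keep_models attach each fold's `monitoring_model` (default TRUE).
#' @return Named list (by patient id) of `monitoring_result`s, each with
#'   the fold's `trajectory_map` (training subset only) and, if provided,
#'   the patient's annotation rows.
#' @export
loo_monitor <- function(records, config = spm_config(), annotations = NULL,
                        keep_models = TRUE) {
  if (length(records) < 3L)
    stop_data("leave-one-out monitoring needs at least 3 patients")
  ids <- vapply(records, `[[`, "", "patient_id")
  out <- lapply(seq_along(records), function(i) {
    model <- fit_monitoring_model(records[-i], config)
    res <- monitor_patient(records[[i]], model)
    res$trajectory_map <- trajectory_map(records[-i])
    if (!is.null(annotations))
      res$annotations <- annotations[annotations$patient_id == ids[i], ,
                                     drop = FALSE]
    if (keep_models) res$model <- model
    res
  })
  setNames(out, ids)
}

#' Run the full monitoring pipeline from a configuration file
#'
#' The configuration (YAML file or equivalent list) names either a
#' synthetic-generation block or input CSVs, an output directory, and
#' parameter overrides:
#'
#' ```yaml
#' output: out/run1
#' synthetic: {n_patients: 10, horizon: 1440, seed: 42,
#'             dropout_fraction: 0.0063, outlier_fraction: 0.0263}
#' # or: input: {kind: raw, paths: [cohort.csv]}
#' # or: input: {kind: gridded, paths: [traces.csv]}
#' horizon: 1440
#' annotations: notes.csv        # optional
#' params: {pca: {c: 3}, charts: {alpha: 0.01}}
#' ```
#'
#' Artifacts written: per-patient chart tables (`charts/<id>.csv`), the
#' all-patient trajectory map (`trajectory_map.csv`), per-fold model
#' bundles (`models/`), and a run log with parameters, fold composition
#' and the per-patient and pooled preprocessing report (dropout/outlier
#' percentages).
#'
#' @param config path to a YAML file, or a list with the same structure.
#' @param out_dir output directory; overrides `config$output`.
#' @return Invisibly, a list with `records`, `results`, `reports`, and
#'   `paths` of the written artifacts.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_format("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_format("config must be a YAML file or a list")
  out_dir <- out_dir %||% config$output
  if (is.null(out_dir)) stop_format("config must name an output directory")
  dir.create(file.path(out_dir, "charts"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "models"), showWarnings = FALSE)
  cfg <- do.call(spm_config, as.list(config$params %||% list()))
  horizon <- as.integer(config$horizon %||% 10080L)

  reports <- NULL
  if (!is.null(config$synthetic)) {
    sy <- config$synthetic
    if (is.null(sy$seed)) stop_format("synthetic block requires a seed")
    cohort <- generate_cohort(default_template(),
                              n_patients = as.integer(sy$n_patients %||% 10L),
                              horizon = horizon, seed = as.integer(sy$seed))
    if ((sy$dropout_fraction %||% 0) > 0 || (sy$outlier_fraction %||% 0) > 0)
      cohort <- lapply(cohort, function(p) {
        p$streams <- inject_missingness(
          p$streams, sy$dropout_fraction %||% 0, sy$outlier_fraction %||% 0,
          seed = as.integer(sy$seed) + match(p$patient_id,
                                             vapply(cohort, `[[`, "",
                                                    "patient_id")),
          template = attr(cohort, "template"))
        p
      })
    write_raw_streams(cohort, file.path(out_dir, "cohort_raw.csv"))
    prep <- lapply(cohort, function(p)
      preprocess_patient(p$streams, horizon, cfg))
    records <- lapply(prep, `[[`, "record")
    reports <- lapply(prep, `[[`, "report")
  } else if (!is.null(config$input)) {
    paths <- unlist(config$input$paths)
    if (is.null(paths) || !all(file.exists(paths)))
      stop_format("input paths missing or not found")
    kind <- config$input$kind %||% "gridded"
    if (kind == "raw") {
      raw <- unlist(lapply(paths, read_raw_streams), recursive = FALSE)
      prep <- lapply(raw, function(p)
        preprocess_patient(p$streams, horizon, cfg))
      records <- lapply(prep, `[[`, "record")
      reports <- lapply(prep, `[[`, "report")
    } else if (kind == "gridded") {
      records <- read_cohort(paths, horizon, cfg$exclusion$threshold)
    } else stop_format("input kind must be 'raw' or 'gridded'")
  } else stop_format("config needs either a synthetic block or input paths")

  annotations <- if (!is.null(config$annotations))
    read_annotations(config$annotations, horizon)
  results <- loo_monitor(records, cfg, annotations = annotations)

  tm <- trajectory_map(records)
  data.table::fwrite(data.table::as.data.table(unclass(tm)),
                     file.path(out_dir, "trajectory_map.csv"))
  chart_paths <- vapply(results, function(res) {
    p <- file.path(out_dir, "charts", paste0(res$patient_id, ".csv"))
    write_chart_table(res$charts, p)
    p
  }, "")
  for (res in results) {
    if (!is.null(res$model)) {
      stem <- file.path(out_dir, "models", paste0("fold_", res$patient_id))
      write_latent_models(res$model$pca, res$model$sfa,
                          paste0(stem, "_latent.json"))
      write_normalization(res$model$normalization,
                          paste0(stem, "_normalization.csv"))
    }
  }
  log_path <- file.path(out_dir, "run_log.txt")
  log_lines <- c(
    "hemospm run log", paste0("date: ", format(Sys.time())),
    paste0("horizon: ", horizon),
    "parameters:", strsplit(yaml::as.yaml(cfg), "\n")[[1L]],
    "folds (held-out <- training):",
    vapply(results, function(res)
      sprintf("  %s <- %s", res$patient_id,
              paste(res$model$train_ids %||% "?", collapse = ",")), ""),
    "preprocessing report:")
  if (!is.null(reports)) {
    per <- vapply(reports, function(r)
      sprintf("  %s: dropouts %.2f%%, outliers %.2f%%, pre/post gaps %.2f%%",
              r$patient_id, 100 * r$dropout_fraction,
              100 * r$outlier_fraction, 100 * r$prepost_fraction), "")
    pooled <- sprintf(
      "  pooled: dropouts %.2f%%, outliers %.2f%% of the evaluated span; pre/post gaps %.2f%% of the horizon",
      100 * sum(vapply(reports, `[[`, 0, "n_dropout")) /
        sum(vapply(reports, `[[`, 0, "n_total")),
      100 * sum(vapply(reports, `[[`, 0, "n_outlier")) /
        sum(vapply(reports, `[[`, 0, "n_total")),
      100 * mean(vapply(reports, `[[`, 0, "prepost_fraction")))
    log_lines <- c(log_lines, per, pooled)
  } else {
    log_lines <- c(log_lines, "  (gridded input: no preprocessing run)")
  }
  writeLines(log_lines, log_path)
  invisible(list(records = records, results = results, reports = reports,
                 paths = list(out_dir = out_dir, charts = chart_paths,
                              trajectory_map = file.path(out_dir,
                                                         "trajectory_map.csv"),
                              log = log_path)))
}
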