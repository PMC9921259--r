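# End-to-end orchestration of the hybrid flow: simulate or load records,
# preprocess, segment into labelled beats, split subjects 70/30, train the
# CNN on the training subjects, extract features for both splits, fit one
# SVR per BP target with cross-validated grid search, predict the test
# split and report metrics plus AAMI compliance.

#' Pipeline configuration
#'
#' @param n_subjects,duration,cohort_args Simulator settings
#'   ([generate_cohort()]); `cohort_args` is a named list of extra generator
#'   arguments. Ignored when `records` are passed to [run_hybrid()].
#' @param split_fraction Fraction of subjects assigned to training.
#' @param split_unit Must be `"subject"`; splitting by beat would leak test
#'   subjects into training and is rejected.
#' @param preprocess,peak,cnn,train,svr Stage sub-configurations.
#' @param svr_beats_per_subject Beats per training subject used for the SVR
#'   stage (the CNN always trains on all beats); caps the quadratic kernel
#'   cost on long records whose beats are highly redundant.
#' @param accuracy_tolerance Tolerance (mmHg) for the accuracy metric.
#' @param global_seed Single seed fanned out to named substreams
#'   (simulator, split, CNN init/shuffle, CV folds).
#' @return An object of class `bp_pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 40, duration = 420,
                            cohort_args = list(),
                            split_fraction = 0.70, split_unit = "subject",
                            preprocess = preprocess_config(),
                            peak = peak_config(),
                            cnn = cnn_config(),
                            train = train_config(),
                            svr = svr_config(),
                            svr_beats_per_subject = 80L,
                            accuracy_tolerance = 5,
                            global_seed = 1L) {
  if (!identical(split_unit, "subject")) {
    stop_cuffbp("split_unit must be \"subject\": beat-level splits leak test subjects into training")
  }
  check_number(split_fraction, "split_fraction", 1e-9, 1 - 1e-9)
  structure(list(n_subjects = n_subjects, duration = duration,
                 cohort_args = cohort_args,
                 split_fraction = split_fraction, split_unit = split_unit,
                 preprocess = preprocess, peak = peak, cnn = cnn,
                 train = train, svr = svr,
                 svr_beats_per_subject = as.integer(svr_beats_per_subject),
                 accuracy_tolerance = accuracy_tolerance,
                 global_seed = as.integer(global_seed)),
            class = "bp_pipeline_config")
}

#' Reference synthetic study configuration
#'
#' The study conditions used throughout the package's own evaluation: a
#' low-noise cohort of 60-bpm subjects recorded for seven minutes (420
#' nominal beats each), waveform noise at 2% of the R amplitude, 1 mmHg BP
#' label noise, strong inverse PTT-to-BP coupling, a subject-disjoint 70/30
#' split and 10 CNN training epochs.
#'
#' @param n_subjects Cohort size.
#' @param seed Global seed.
#' @param epochs CNN training epochs.
#' @param duration Seconds of signal per subject.
#' @return A [pipeline_config()].
#' @export
synthetic_study_config <- function(n_subjects = 40, seed = 1L, epochs = 10,
                                   duration = 420) {
  pipeline_config(
    n_subjects = n_subjects, duration = duration,
    cohort_args = list(hr_range = c(60, 60)),
    train = train_config(epochs = epochs),
    global_seed = seed
  )
}

#' Split subjects into disjoint train and test sets
#'
#' @param subject_ids Unique subject identifiers (>= 2).
#' @param fraction Training fraction; `round(fraction * n)` subjects train.
#' @param seed Seed for the shuffle.
#' @return List with `train` and `test` id vectors (disjoint, exhaustive).
#' @export
#' @examples
#' split_subjects(sprintf("S%03d", 1:120), 0.70, seed = 1) # 84 / 36
split_subjects <- function(subject_ids, fraction = 0.70, seed = 1L) {
  n <- length(subject_ids)
  if (n < 2) stop_cuffbp("need at least 2 subjects to split")
  n_train <- round(fraction * n)
  n_train <- min(max(n_train, 1L), n - 1L)
  shuffled <- with_seed(derive_seed(seed, "split"), sample(subject_ids))
  list(train = sort(shuffled[seq_len(n_train)]),
       test = sort(shuffled[(n_train + 1):n]))
}

subset_beats <- function(beats, keep) {
  structure(list(
    ecg_beats = beats$ecg_beats[keep, , drop = FALSE],
    ppg_beats = beats$ppg_beats[keep, , drop = FALSE],
    r_index = beats$r_index[keep],
    sbp = beats$sbp[keep],
    dbp = beats$dbp[keep],
    subject_id = beats$subject_id[keep],
    n_dropped = beats$n_dropped
  ), class = "bp_beats")
}

#' Run the full hybrid CNN-SVR pipeline
#'
#' Executes simulate/load -> preprocess -> segment -> subject split -> CNN
#' training (training subjects only) -> feature extraction (both splits) ->
#' SVR grid fit with grouped cross-validation (training subjects only) ->
#' prediction and evaluation on the test split. No test-subject beat enters
#' CNN training, feature scaling statistics, or SVR fitting; the returned
#' manifest records the provenance of every stage.
#'
#' @param config A [pipeline_config()].
#' @param records Optional list of [bp_record()]s; when `NULL` a synthetic
#'   cohort is generated from the config.
#' @param verbose Log stage progress.
#' @return A list of class `bp_run`: `split`, `cnn` (trained model), `svr`
#'   (two models), `predictions` (data.frame with subject, beat time,
#'   predicted and true SBP/DBP), `metrics`, `aami`, `log`, `config`.
#' @export
run_hybrid <- function(config = pipeline_config(), records = NULL,
                       verbose = TRUE) {
  lg <- new.env()
  seed <- config$global_seed
  if (is.null(records)) {
    log_line("simulating %d subjects x %.0f s", config$n_subjects,
             config$duration, collector = lg, verbose = verbose)
    records <- do.call(generate_cohort,
                       c(list(n_subjects = config$n_subjects,
                              duration = config$duration,
                              seed = derive_seed(seed, "simulator")),
                         config$cohort_args))
  }
  beats_by_subj <- lapply(records, function(rec) {
    pre <- preprocess_record(rec, config$preprocess)
    segment_record(pre, config$peak)
  })
  beats <- bind_beats(beats_by_subj)
  log_line("segmented %d beats from %d record(s) (%d dropped)",
           nrow(beats$ecg_beats), length(records), beats$n_dropped,
           collector = lg, verbose = verbose)

  ids <- unique(beats$subject_id)
  split <- split_subjects(ids, config$split_fraction, seed)
  tr <- beats$subject_id %in% split$train
  beats_tr <- subset_beats(beats, tr)
  beats_te <- subset_beats(beats, !tr)
  log_line("split: %d train / %d test subjects; %d / %d beats",
           length(split$train), length(split$test),
           nrow(beats_tr$ecg_beats), nrow(beats_te$ecg_beats),
           collector = lg, verbose = verbose)

  arr_tr <- beats_to_array(beats_tr)
  cnn <- cnn_build(config$cnn, seed = derive_seed(seed, "cnn"))
  tc <- config$train
  tc$seed <- derive_seed(seed, "cnn-train")
  cnn <- cnn_train(cnn, arr_tr$x, arr_tr$y, tc, verbose = verbose)
  log_line("CNN trained: half-MSE %.2f -> %.2f over %d epochs",
           cnn$loss_history[1], cnn$loss_history[length(cnn$loss_history)],
           length(cnn$loss_history), collector = lg, verbose = verbose)

  feats_tr <- cnn_features(cnn, arr_tr$x)
  arr_te <- beats_to_array(beats_te)
  feats_te <- cnn_features(cnn, arr_te$x)

  svr_sel <- svr_subsample(beats_tr$subject_id, config$svr_beats_per_subject,
                           seed)
  log_line("SVR training set: %d of %d training beats", length(svr_sel),
           nrow(feats_tr), collector = lg, verbose = verbose)
  svr_models <- list(
    SBP = fit_svr(feats_tr[svr_sel, , drop = FALSE], beats_tr$sbp[svr_sel],
                  config$svr, seed = derive_seed(seed, "svr-sbp"),
                  subject_ids = beats_tr$subject_id[svr_sel],
                  target_name = "SBP"),
    DBP = fit_svr(feats_tr[svr_sel, , drop = FALSE], beats_tr$dbp[svr_sel],
                  config$svr, seed = derive_seed(seed, "svr-dbp"),
                  subject_ids = beats_tr$subject_id[svr_sel],
                  target_name = "DBP")
  )
  for (m in svr_models) {
    log_line("SVR %s: C=%g gamma(nominal)=%g eps=%g, %d SVs, CV MAE %.2f",
             m$target_name, m$C, m$gamma_nominal, m$epsilon,
             length(m$dual_coef), min(m$cv_report$mae),
             collector = lg, verbose = verbose)
  }

  sbp_pred <- predict(svr_models$SBP, feats_te)
  dbp_pred <- predict(svr_models$DBP, feats_te)
  predictions <- data.frame(
    subject_id = beats_te$subject_id,
    beat_time_s = (beats_te$r_index - 1) / 125,
    sbp_pred = sbp_pred, dbp_pred = dbp_pred,
    sbp_true = beats_te$sbp, dbp_true = beats_te$dbp
  )
  metrics <- metrics_report(sbp_pred, beats_te$sbp, dbp_pred, beats_te$dbp,
                            tolerance = config$accuracy_tolerance)
  aami <- aami_check(metrics, n_subjects = length(ids))
  log_line("test MAE: SBP %.2f, DBP %.2f mmHg; error SD: %.2f / %.2f",
           metrics$SBP$mae, metrics$DBP$mae,
           metrics$SBP$std_err, metrics$DBP$std_err,
           collector = lg, verbose = verbose)

  structure(list(split = split, cnn = cnn, svr = svr_models,
                 predictions = predictions, metrics = metrics, aami = aami,
                 manifest = list(train_subjects = split$train,
                                 test_subjects = split$test,
                                 cnn_trained_on = split$train,
                                 svr_trained_on = split$train,
                                 scaler_fit_on = split$train),
                 log = lg$lines, config = config),
            class = "bp_run")
}

svr_subsample <- function(subject_id, per_subject, seed) {
  idx <- split(seq_along(subject_id), subject_id)
  sel <- with_seed(derive_seed(seed, "svr-subsample"), {
    lapply(idx, function(i) {
      if (length(i) <= per_subject) i else sort(sample(i, per_subject))
    })
  })
  unlist(sel, use.names = FALSE)
}

#' Predict per-beat BP for a new record with trained artifacts
#'
#' Inference-only path: preprocesses the record, detects beats, extracts
#' CNN features and applies both SVR models. No BP labels are required.
#'
#' @param artifacts A `bp_run` from [run_hybrid()].
#' @param record A [bp_record()] with ECG and `PLETH` channels.
#' @return A data.frame with `subject_id`, `beat_time_s`, `sbp_pred`,
#'   `dbp_pred` (one row per detected beat; empty with a warning for an
#'   empty record).
#' @export
run_predict <- function(artifacts, record) {
  if (!"PLETH" %in% names(record$channels)) {
    stop_cuffbp("record is missing the PLETH channel")
  }
  cfg <- artifacts$config
  if (record$length < cfg$preprocess$sg_window) {
    warning("record too short to segment; returning an empty table", call. = FALSE)
    return(data.frame(subject_id = character(0), beat_time_s = numeric(0),
                      sbp_pred = numeric(0), dbp_pred = numeric(0)))
  }
  pre <- preprocess_record(record, cfg$preprocess)
  peaks <- detect_r_peaks(pre$channels[["ECG_norm"]], cfg$peak)
  if (!length(peaks)) {
    warning("no beats detected; returning an empty table", call. = FALSE)
    return(data.frame(subject_id = character(0), beat_time_s = numeric(0),
                      sbp_pred = numeric(0), dbp_pred = numeric(0)))
  }
  beats <- segment_beats(pre$channels[["ECG_norm"]], pre$channels[["PLETH_norm"]],
                         peaks, record$fs)
  x <- array(0, c(2, ncol(beats$ecg_beats), nrow(beats$ecg_beats)))
  x[1, , ] <- t(beats$ecg_beats)
  x[2, , ] <- t(beats$ppg_beats)
  feats <- cnn_features(artifacts$cnn, x)
  data.frame(
    subject_id = record$source_id,
    beat_time_s = (peaks - 1) / record$fs,
    sbp_pred = predict(artifacts$svr$SBP, feats),
    dbp_pred = predict(artifacts$svr$DBP, feats)
  )
}
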