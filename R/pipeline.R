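#' Full-pipeline configuration
#'
#' Bundles every stage's parameters: data source (synthetic cohort config
#' or a directory of recordings), segmentation, feature extraction,
#' ReliefF, common-channel selection, fusion, classifier, and the
#' evaluation protocol.
#'
#' @param synthetic A [synth_cohort_config()] used when `data_dir` is NULL.
#' @param data_dir Optional directory of recording files named
#'   `<subject>_state<0|1>.csv` (or `.edf`).
#' @param epoch_len,overlap Segmentation, in seconds.
#' @param features Feature subset (default: all five).
#' @param m,r_factor Sample-entropy parameters.
#' @param relieff A [relief_config()].
#' @param selection_method `"accuracy"` (accuracy-weighted common
#'   channels), `"addition"` (normalized weight addition), or `"none"`
#'   (keep all channels).
#' @param n_keep Channels kept after selection (default: half).
#' @param global_selection Select channels once from all epochs instead of
#'   per training split (reproduces a select-once protocol; the default
#'   per-split selection is leakage-safe).
#' @param fusion_method `"sparse"`, `"pca"`, or `"concat"`.
#' @param M,T0 Sparse-fusion dictionary size and OMP sparsity.
#' @param reg_alpha SRDA ridge penalty.
#' @param evaluation `"split_75_25_x5"` (default: `n_reps` seeded
#'   stratified 75/25 splits) or `"kfold_5"` (stratified 5-fold CV).
#' @param n_reps Number of random splits in split mode (default 5).
#' @param train_fraction Training fraction in split mode (default 0.75).
#' @param cv_folds Folds for the single-channel accuracy estimates.
#' @param include_single_features Also evaluate each feature type alone
#'   (the per-feature comparison table).
#' @param seed Master seed; all stage seeds derive from it.
#' @param verbose Log stage timings with [message()].
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synth_cohort_config(),
                            data_dir = NULL, epoch_len = 1, overlap = 0,
                            features = feature_names_canonical(),
                            m = 2L, r_factor = 0.2,
                            relieff = relief_config(),
                            selection_method = c("accuracy", "addition", "none"),
                            n_keep = NULL, global_selection = FALSE,
                            fusion_method = c("sparse", "pca", "concat"),
                            M = 20L, T0 = 5L, reg_alpha = 0.01,
                            evaluation = c("split_75_25_x5", "kfold_5"),
                            n_reps = 5L, train_fraction = 0.75,
                            cv_folds = 5L, include_single_features = TRUE,
                            seed = 1L, verbose = FALSE) {
  structure(list(synthetic = synthetic, data_dir = data_dir,
                 epoch_len = epoch_len, overlap = overlap,
                 features = features, m = m, r_factor = r_factor,
                 relieff = relieff,
                 selection_method = match.arg(selection_method),
                 n_keep = n_keep, global_selection = global_selection,
                 fusion_method = match.arg(fusion_method), M = M, T0 = T0,
                 reg_alpha = reg_alpha, evaluation = match.arg(evaluation),
                 n_reps = as.integer(n_reps),
                 train_fraction = train_fraction, cv_folds = cv_folds,
                 include_single_features = include_single_features,
                 seed = as.integer(seed), verbose = verbose),
            class = "pipeline_config")
}

pipeline_log <- function(cfg, state, fmt, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%OS1"),
                  sprintf(fmt, ...))
  if (cfg$verbose) message(line)
  state$log <- c(state$log, line)
  invisible(NULL)
}

with_stage <- function(stage, subject, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "'",
         if (!is.null(subject)) paste0(" (subject ", subject, ")") else "",
         ": ", conditionMessage(e), call. = FALSE))
}

# per-class stratified train indicator for a single split
stratified_split <- function(y, frac, seed) {
  set.seed(seed)
  train <- logical(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    train[idx[seq_len(round(frac * length(idx)))]] <- TRUE
  }
  train
}

# derive a stage seed from the master seed; stays far below 2^31 for the
# small master seeds used in practice
derive_seed <- function(seed, offset) (seed %% 100000L) * 1000L + offset

pipeline_load_subjects <- function(cfg, state) {
  if (is.null(cfg$data_dir)) {
    cohort <- with_stage("simulate", NULL, generate_cohort(cfg$synthetic))
    recs <- cohort$recordings
    state$ground_truth <- cohort$ground_truth
  } else {
    files <- list.files(cfg$data_dir, pattern = "_state[01]\\.(csv|edf)$",
                        full.names = TRUE)
    if (!length(files)) stop("no recordings found in ", cfg$data_dir)
    recs <- lapply(files, function(f) {
      base <- sub("\\.(csv|edf)$", "", basename(f))
      sid <- sub("_state[01]$", "", base)
      st <- as.integer(sub("^.*_state", "", base))
      load_recording(f, subject_id = sid, state = st)
    })
  }
  split(recs, vapply(recs, `[[`, "", "subject_id"))
}

# segment + feature-extract every subject; returns list of feature_matrix
pipeline_features <- function(cfg, state) {
  by_subject <- pipeline_load_subjects(cfg, state)
  lapply(by_subject, function(recs) {
    sid <- recs[[1L]]$subject_id
    with_stage("features", sid, {
      eps <- bind_epoch_sets(lapply(recs, segment, epoch_len = cfg$epoch_len,
                                    overlap = cfg$overlap))
      extract_features(eps, cfg$features, m = cfg$m,
                       r_factor = cfg$r_factor)
    })
  })
}

# everything the classification stage needs: features, split per rep, and
# (when selection is on) the per-rep weight tables and channel rankings
pipeline_prepare <- function(cfg, subject_features = NULL) {
  state <- new.env()
  state$log <- character()
  t0 <- Sys.time()
  if (is.null(subject_features))
    subject_features <- pipeline_features(cfg, state)
  pipeline_log(cfg, state, "features ready for %d subjects (%.1f s)",
               length(subject_features),
               as.numeric(difftime(Sys.time(), t0, units = "secs")))
  n_reps <- if (cfg$evaluation == "kfold_5") 5L else cfg$n_reps
  kfolds <- if (cfg$evaluation == "kfold_5")
    lapply(subject_features, function(fm)
      stratified_folds(fm$labels, 5L, derive_seed(cfg$seed, 999L)))
  need_sel <- cfg$selection_method != "none"
  global <- NULL
  if (need_sel && cfg$global_selection)
    global <- pipeline_selection(cfg, subject_features,
                                 lapply(subject_features, function(fm)
                                   rep(TRUE, length(fm$labels))), 0L)
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    t1 <- Sys.time()
    train <- if (cfg$evaluation == "kfold_5") {
      lapply(kfolds, function(f) f != r)
    } else {
      lapply(subject_features, function(fm)
        stratified_split(fm$labels, cfg$train_fraction,
                         derive_seed(cfg$seed, r)))
    }
    sel <- if (!need_sel) NULL
           else if (cfg$global_selection) global
           else pipeline_selection(cfg, subject_features, train, r)
    reps[[r]] <- list(train = train, selection = sel)
    if (need_sel)
      pipeline_log(cfg, state, "rep %d selection [%s]: %s (%.1f s)", r,
                   cfg$selection_method,
                   paste(sel$channels[[cfg$selection_method]], collapse = " "),
                   as.numeric(difftime(Sys.time(), t1, units = "secs")))
  }
  list(cfg = cfg, features = subject_features, reps = reps,
       log = state$log,
       ground_truth = if (!is.null(state$ground_truth)) state$ground_truth)
}

# ReliefF weights + single-channel accuracies on the training epochs only,
# aggregated into both common-channel rankings
pipeline_selection <- function(cfg, subject_features, train, rep_id) {
  train_fms <- Map(function(fm, tr) subset_features(fm, rows = which(tr)),
                   subject_features, train)
  table <- with_stage("channel-selection", NULL,
    compute_channel_weight_table(train_fms, cfg$relieff, with_acc = TRUE,
                                 cv_folds = cfg$cv_folds,
                                 seed = derive_seed(cfg$seed, 500L + rep_id),
                                 reg_alpha = cfg$reg_alpha))
  n_ch <- length(table$channel_labels)
  n_keep <- if (is.null(cfg$n_keep)) floor(n_ch / 2) else cfg$n_keep
  chans <- list(
    accuracy = select_common_channels(common_weights_accuracy(table), n_keep),
    addition = select_common_channels(common_weights_addition(table), n_keep))
  list(table = table, channels = chans, n_keep = n_keep)
}

# fit/evaluate one subject on one split with one fusion method
classify_split <- function(cfg, fm, train, channels, fusion_method, rep_id) {
  fm_use <- if (is.null(channels)) fm else subset_features(fm, channels)
  tr <- subset_features(fm_use, rows = which(train))
  te <- subset_features(fm_use, rows = which(!train))
  fused <- switch(fusion_method,
    sparse = fuse_sparse(tr, te, M = min(cfg$M, sum(train)), T0 = cfg$T0,
                         seed = derive_seed(cfg$seed, 100L + rep_id)),
    pca = fuse_pca(tr, te, n_components = min(cfg$M, sum(train),
                                              ncol(tr$values))),
    concat = fuse_concat(tr, te))
  model <- srda_fit(fused$train, tr$labels, cfg$reg_alpha)
  pred <- srda_predict(model, fused$test)
  evaluate_predictions(te$labels, pred)
}

# evaluate every subject over every rep; channel_set is "full" or a
# selection-ranking name ("accuracy"/"addition")
pipeline_classify <- function(prep, fusion_method = NULL,
                              channel_set = NULL) {
  cfg <- prep$cfg
  if (is.null(fusion_method)) fusion_method <- cfg$fusion_method
  if (is.null(channel_set))
    channel_set <- if (cfg$selection_method == "none") "full"
                   else cfg$selection_method
  subjects <- names(prep$features)
  res <- list()
  for (r in seq_along(prep$reps)) {
    rep <- prep$reps[[r]]
    chans <- if (channel_set == "full") NULL
             else rep$selection$channels[[channel_set]]
    for (s in subjects) {
      met <- with_stage(paste0("classify-", fusion_method), s,
        classify_split(cfg, prep$features[[s]], rep$train[[s]], chans,
                       fusion_method, r))
      res[[length(res) + 1L]] <-
        data.frame(subject = s, rep = r, accuracy = met$accuracy,
                   precision = met$precision, f1 = met$f1)
    }
  }
  do.call(rbind, res)
}

# per-feature-type accuracies (no fusion), same splits/channels
pipeline_single_features <- function(prep, channel_set = NULL) {
  cfg <- prep$cfg
  if (is.null(channel_set))
    channel_set <- if (cfg$selection_method == "none") "full"
                   else cfg$selection_method
  res <- list()
  for (r in seq_along(prep$reps)) {
    rep <- prep$reps[[r]]
    chans <- if (channel_set == "full") NULL
             else rep$selection$channels[[channel_set]]
    for (s in names(prep$features)) {
      fm <- prep$features[[s]]
      fm_use <- if (is.null(chans)) fm else subset_features(fm, chans)
      for (f in unique(fm_use$features)) {
        ff <- subset_features(fm_use, features = f)
        tr_idx <- which(rep$train[[s]])
        model <- srda_fit(ff$values[tr_idx, , drop = FALSE],
                          ff$labels[tr_idx], cfg$reg_alpha)
        pred <- srda_predict(model, ff$values[-tr_idx, , drop = FALSE])
        res[[length(res) + 1L]] <-
          data.frame(subject = s, rep = r, feature = f,
                     accuracy = mean(pred == ff$labels[-tr_idx]))
      }
    }
  }
  do.call(rbind, res)
}

summarize_metrics <- function(df) {
  agg <- function(col) {
    m <- tapply(df[[col]], df$subject, mean)
    s <- tapply(df[[col]], df$subject, stats::sd)
    s[is.na(s)] <- 0
    list(mean = m, sd = s)
  }
  a <- agg("accuracy"); p <- agg("precision"); f <- agg("f1")
  data.frame(subject = names(a$mean),
             accuracy_mean = as.numeric(a$mean), accuracy_sd = as.numeric(a$sd),
             precision_mean = as.numeric(p$mean), precision_sd = as.numeric(p$sd),
             f1_mean = as.numeric(f$mean), f1_sd = as.numeric(f$sd),
             row.names = NULL)
}

#' Run the full fatigue-detection pipeline
#'
#' Per subject: segment recordings into epochs, extract the five features,
#' rank channels with ReliefF plus the configured common-channel scheme on
#' the training epochs of each split, restrict to the selected channels,
#' fuse the features, classify with SRDA, and aggregate the metrics over
#' splits. Channel selection, fusion dictionaries, and classifiers are fit
#' strictly on training data within each split; all randomness derives
#' from the config seed.
#'
#' @param cfg A [pipeline_config()].
#' @return An `evaluation_report`: per-subject metric table
#'   (mean and sd of accuracy/precision/F1), per-feature single-feature
#'   accuracies with the fused accuracy alongside, selected channels per
#'   split, and a runtime log.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  prep <- pipeline_prepare(cfg)
  fused <- pipeline_classify(prep)
  singles <- if (cfg$include_single_features) pipeline_single_features(prep)
  single_table <- NULL
  if (!is.null(singles)) {
    wide <- tapply(singles$accuracy, list(singles$subject, singles$feature),
                   mean)
    single_table <- data.frame(subject = rownames(wide),
                               as.data.frame(wide[, intersect(
                                 feature_names_canonical(), colnames(wide)),
                                 drop = FALSE]),
                               fused = as.numeric(
                                 tapply(fused$accuracy, fused$subject, mean)),
                               row.names = NULL)
  }
  structure(list(per_subject = summarize_metrics(fused),
                 per_rep = fused, single_features = single_table,
                 selected_channels = lapply(prep$reps, function(r)
                   if (!is.null(r$selection))
                     r$selection$channels[[if (cfg$selection_method == "none")
                       "accuracy" else cfg$selection_method]]),
                 ground_truth = prep$ground_truth, log = prep$log,
                 cfg = cfg),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  cat(sprintf("  fusion: %s; channel selection: %s; evaluation: %s\n",
              x$cfg$fusion_method, x$cfg$selection_method,
              x$cfg$evaluation))
  print(x$per_subject, digits = 3)
  if (!is.null(x$selected_channels[[1L]]))
    cat("  selected channels (split 1):",
        paste(x$selected_channels[[1L]], collapse = ", "), "\n")
  invisible(x)
}

#' Compare the three fusion methods on identical splits
#'
#' Runs the pipeline once per fusion method with shared data, splits, and
#' channel selections, so the methods differ only in the fusion stage.
#'
#' @param cfg A [pipeline_config()].
#' @return A list with `accuracy` (data.frame subject x method mean
#'   accuracies), the per-rep `detail`, and the shared `prep`'s selected
#'   channels.
#' @export
compare_fusions <- function(cfg = pipeline_config()) {
  prep <- pipeline_prepare(cfg)
  methods <- c("sparse", "pca", "concat")
  detail <- lapply(methods, function(m) pipeline_classify(prep, m))
  names(detail) <- methods
  acc <- data.frame(subject = sort(unique(detail[[1L]]$subject)))
  for (m in methods)
    acc[[m]] <- as.numeric(tapply(detail[[m]]$accuracy,
                                  detail[[m]]$subject, mean))
  list(accuracy = acc, detail = detail,
       selected_channels = lapply(prep$reps, function(r)
         if (!is.null(r$selection)) r$selection$channels),
       splits = lapply(prep$reps, `[[`, "train"))
}

#' Compare full-channel and selected-channel classification
#'
#' Shares data, splits and weight tables across three channel sets: all
#' channels, the accuracy-weighted top half, and the weight-addition top
#' half.
#'
#' @param cfg A [pipeline_config()] (its `selection_method` must not be
#'   `"none"`).
#' @return A list with `accuracy` (subject x channel-set means), per-rep
#'   `detail`, and the per-rep channel rankings.
#' @export
compare_channel_selection <- function(cfg = pipeline_config()) {
  if (cfg$selection_method == "none")
    stop("selection_method must be 'accuracy' or 'addition'")
  prep <- pipeline_prepare(cfg)
  sets <- c("full", "accuracy", "addition")
  detail <- lapply(sets, function(s)
    pipeline_classify(prep, cfg$fusion_method, channel_set = s))
  names(detail) <- sets
  acc <- data.frame(subject = sort(unique(detail[[1L]]$subject)))
  for (s in sets)
    acc[[s]] <- as.numeric(tapply(detail[[s]]$accuracy,
                                  detail[[s]]$subject, mean))
  list(accuracy = acc, detail = detail,
       selections = lapply(prep$reps, function(r) r$selection$channels))
}
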