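# Lazily computed, memoised full-scale synthetic evaluations shared by the
# acceptance suite: each seed's cohort is generated once, features are
# extracted once, and the single-split pipeline quantities are reused by
# every property that needs them.

.cohort_memo <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cohort_memo[[key]])) .cohort_memo[[key]] <- force(expr)
  .cohort_memo[[key]]
}

acceptance_seeds <- function() 1:10

informative_labels_default <- function() c("Cz", "FCz", "F3", "F4", "C3", "C4")

# seed 1's cohort is kept (other seeds' raw signals are discarded after
# feature extraction to bound memory)
acc_cohort_seed1 <- function() {
  memo("cohort1", generate_cohort(synth_cohort_config(seed = 1L)))
}

acc_features <- function(seed) {
  memo(paste0("features", seed), {
    cohort <- if (seed == 1L) acc_cohort_seed1()
              else generate_cohort(synth_cohort_config(seed = seed))
    by_subject <- split(cohort$recordings,
                        vapply(cohort$recordings, `[[`, "", "subject_id"))
    lapply(by_subject, function(recs)
      extract_features(bind_epoch_sets(lapply(recs, segment))))
  })
}

# one stratified 75/25 split per seed: channel selection fitted on the
# training epochs, then accuracies of every fusion route and channel set
acc_eval <- function(seed) {
  memo(paste0("eval", seed), {
    cfg <- pipeline_config(synthetic = synth_cohort_config(seed = seed),
                           n_reps = 1L, seed = seed)
    prep <- eegfatigue:::pipeline_prepare(cfg,
                                          subject_features = acc_features(seed))
    mean_acc <- function(method, channels)
      mean(eegfatigue:::pipeline_classify(prep, method, channels)$accuracy)
    singles <- eegfatigue:::pipeline_single_features(prep, "accuracy")
    list(selection = prep$reps[[1L]]$selection$channels,
         sparse_selected = mean_acc("sparse", "accuracy"),
         sparse_full = mean_acc("sparse", "full"),
         pca_selected = mean_acc("pca", "accuracy"),
         concat_selected = mean_acc("concat", "accuracy"),
         single_features = tapply(singles$accuracy, singles$feature, mean))
  })
}
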