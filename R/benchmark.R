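# Parameter-recovery benchmark on a synthetic world: can the two-stage model
# recover the latent compatibility structure the generator planted? This is
# the package's standing end-to-end check; the defaults define the benchmark
# conditions, and the model configuration is sized so the whole run finishes
# in minutes on one CPU (a 512-bit fingerprint fold and mid-sized layers are
# ample for vocabularies of this size).

#' End-to-end parameter-recovery benchmark
#'
#' Simulates a reaction world, trains both stages, and measures: held-out
#' example-based F1 for the reagent and solvent tasks at the validation-
#' optimized threshold; top-k exact-match hit rates; the mean per-reaction
#' Spearman correlation between predicted context scores and latent yields;
#' and temperature MAE against the constant mean/median baselines.
#'
#' @param n_reactions,n_reagents,n_solvents,n_templates world size.
#' @param multi_condition_fraction,yield_noise_sd,temp_noise_sd generator
#'   noise settings.
#' @param candidate,ranking model configurations (benchmark-sized defaults).
#' @param seed integer seed driving world, sampling, split and training.
#' @param verbose print stage progress.
#' @return list with `f1_reagent`, `f1_solvent`, `threshold`, `topk`,
#'   `spearman`, `temperature`, `n_test`, `elapsed_s`.
#' @export
recovery_benchmark <- function(n_reactions = 4000, n_reagents = 40,
                               n_solvents = 15, n_templates = 8,
                               multi_condition_fraction = 0.088,
                               yield_noise_sd = 0.05, temp_noise_sd = 5,
                               candidate = candidate_config(
                                 nbits = 512, hidden = 256,
                                 task_hidden = 64, dropout = 0.2,
                                 epochs = 25, lr = 1.5e-3, batch = 128),
                               ranking = ranking_config(
                                 nbits = 512, fp_hidden = 256,
                                 cond_hidden = 64, trunk_hidden = 128,
                                 epochs = 12, lr = 1.5e-3,
                                 batch_lists = 24),
                               seed = 1, verbose = FALSE) {
  t0 <- Sys.time()
  ranking$radius <- candidate$radius
  ranking$nbits <- candidate$nbits
  world <- make_world(n_reagents, n_solvents, n_templates,
                      seed = derive_seed(seed, 11))
  ds <- sample_dataset(world, n_reactions, multi_condition_fraction,
                       yield_noise_sd, temp_noise_sd,
                       seed = derive_seed(seed, 12))
  vocab <- build_vocabulary(ds$entries)
  split <- grouped_split(ds$entries, seed = derive_seed(seed, 13))
  rxn_log("benchmark: %d entries, %d reagent / %d solvent labels",
          length(ds$entries), nrow(vocab$reagent), nrow(vocab$solvent),
          verbose = verbose)
  candidate$seed <- derive_seed(seed, 14)
  cand <- fit_candidate_model(split$train, vocab, candidate,
                              verbose = verbose)
  threshold <- optimize_threshold(cand, split$validation)$threshold
  rxn_log("benchmark: optimized threshold %.2f", threshold,
          verbose = verbose)
  X_test <- entry_features(split$test, candidate$radius, candidate$nbits)
  probs <- predict(cand, features = X_test)
  Y <- entry_targets(split$test, vocab)
  to_sets <- function(M) apply(M, 1, function(r) which(r > 0.5),
                               simplify = FALSE)
  f1_r <- multilabel_metrics(to_sets(Y$reagent),
                             to_sets(probs$reagent >= threshold),
                             nrow(vocab$reagent))$f1
  f1_s <- multilabel_metrics(to_sets(Y$solvent),
                             to_sets(probs$solvent >= threshold),
                             nrow(vocab$solvent))$f1
  feats_train <- entry_features(split$train, candidate$radius,
                                candidate$nbits)
  lists <- build_training_lists(split$train, cand, features = feats_train)
  ranking$seed <- derive_seed(seed, 15)
  ranker <- fit_ranking_model(lists, split$train, vocab, ranking,
                              features = feats_train, verbose = verbose)
  report <- evaluate_pipeline(split$test, cand, ranker, vocab, threshold)
  spear <- yield_rank_correlation(ranker, split$test, ds$truth,
                                  features = X_test)
  list(f1_reagent = f1_r, f1_solvent = f1_s, threshold = threshold,
       topk = unlist(report$topk$hit_rates),
       spearman = spear$mean_spearman,
       temperature = report$temperature,
       multi_record = report$multi_record,
       n_test = length(split$test),
       elapsed_s = as.numeric(difftime(Sys.time(), t0, "secs")))
}
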