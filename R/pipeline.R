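# End-to-end pipeline: preprocess -> train candidate model -> optimize
# threshold -> mine hard negatives -> train ranking model -> evaluate.
# A single global seed fans out to fixed per-stage seeds so stages are
# individually reproducible; every run directory carries its config,
# manifest and reports.

#' Assemble a pipeline configuration
#'
#' @param data_path reaction-condition table to train on; `NULL` to simulate
#'   a synthetic world instead.
#' @param simulate list of arguments for [make_world()] /
#'   [sample_dataset()] (`n_reagents`, `n_solvents`, `n_templates`,
#'   `n_reactions`, `multi_condition_fraction`, `yield_noise_sd`,
#'   `temp_noise_sd`); used when `data_path` is `NULL`.
#' @param candidate a [candidate_config()].
#' @param ranking a [ranking_config()] (its fingerprint settings are forced
#'   to match the candidate ones).
#' @param min_label_freq,ratios preprocessing parameters.
#' @param threshold fixed candidate cutoff, or `NULL` to optimize on
#'   validation.
#' @param negative_cutoff,negative_cap hard-negative mining parameters.
#' @param top_k_eval the k values evaluated.
#' @param do_ranking toggle for the negative-mining/ranking/recommendation
#'   stages; when `FALSE` the evaluation is limited to candidate metrics and
#'   the report says so.
#' @param seed global seed.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(data_path = NULL,
                            simulate = list(n_reagents = 40, n_solvents = 15,
                                            n_templates = 8,
                                            n_reactions = 2000,
                                            multi_condition_fraction = 0.088,
                                            yield_noise_sd = 0.05,
                                            temp_noise_sd = 5),
                            candidate = candidate_config(),
                            ranking = ranking_config(),
                            min_label_freq = 10,
                            ratios = c(0.8, 0.1, 0.1),
                            threshold = NULL,
                            negative_cutoff = 0.1, negative_cap = 5,
                            top_k_eval = c(1, 3, 10, 20),
                            do_ranking = TRUE,
                            seed = 1) {
  ranking$radius <- candidate$radius
  ranking$nbits <- candidate$nbits
  structure(list(data_path = data_path, simulate = simulate,
                 candidate = candidate, ranking = ranking,
                 min_label_freq = min_label_freq, ratios = ratios,
                 threshold = threshold, negative_cutoff = negative_cutoff,
                 negative_cap = negative_cap, top_k_eval = top_k_eval,
                 do_ranking = do_ranking, seed = seed),
            class = "pipeline_config")
}

#' Run the full recommendation pipeline
#'
#' Executes every stage and, if `out_dir` is given, writes the dataset,
#' vocabulary, split manifest, evaluation report and run manifest there as
#' plain text. Two runs with an identical config produce identical reports.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory (created if missing).
#' @param verbose print stage progress.
#' @return list with `models` (candidate, ranking), `threshold`, `report`
#'   (all evaluation tables), `split`, `vocab`, and `truth` (synthetic runs
#'   only).
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  # stage 1: data
  truth <- NULL
  if (is.null(config$data_path)) {
    rxn_log("stage simulate", verbose = verbose)
    sim <- config$simulate
    world <- make_world(sim$n_reagents, sim$n_solvents, sim$n_templates,
                        seed = derive_seed(config$seed, 1))
    ds <- sample_dataset(world, sim$n_reactions,
                         sim$multi_condition_fraction %||% 0.088,
                         sim$yield_noise_sd %||% 0.05,
                         sim$temp_noise_sd %||% 5,
                         seed = derive_seed(config$seed, 2))
    entries <- ds$entries
    truth <- c(ds$truth, list(world = world))
    if (!is.null(out_dir)) {
      write_dataset(entries, file.path(out_dir, "dataset.tsv"))
    }
  } else {
    rxn_log("stage preprocess: %s", config$data_path, verbose = verbose)
    rd <- read_reaction_table(config$data_path)
    entries <- normalize_labels(rd$entries, rd$name_lookup)$entries
  }
  # stage 2: preprocess + split
  fl <- apply_filters(entries, min_label_freq = config$min_label_freq)
  vocab <- build_vocabulary(fl$entries)
  split <- grouped_split(fl$entries, config$ratios,
                         seed = derive_seed(config$seed, 3))
  # stage 3: candidate model
  rxn_log("stage train-candidate (%d train entries)", length(split$train),
          verbose = verbose)
  cand_cfg <- config$candidate
  cand_cfg$seed <- derive_seed(config$seed, 4)
  cand <- fit_candidate_model(split$train, vocab, cand_cfg,
                              validation = split$validation,
                              verbose = verbose)
  # stage 4: threshold
  threshold <- config$threshold
  if (is.null(threshold)) {
    threshold <- optimize_threshold(cand, split$validation)$threshold
    rxn_log("stage optimize-threshold: %.2f", threshold, verbose = verbose)
  }
  # stage 5: hard negatives + ranking model
  ranker <- NULL
  if (isTRUE(config$do_ranking %||% TRUE)) {
    rxn_log("stage mine-negatives", verbose = verbose)
    feats_train <- entry_features(split$train, cand_cfg$radius,
                                  cand_cfg$nbits)
    lists <- build_training_lists(split$train, cand, features = feats_train,
                                  cutoff = config$negative_cutoff,
                                  cap = config$negative_cap)
    rxn_log("stage train-ranking (%d lists, %d contexts)", length(lists),
            sum(vapply(lists, `[[`, numeric(1), "n")), verbose = verbose)
    rank_cfg <- config$ranking
    rank_cfg$seed <- derive_seed(config$seed, 5)
    ranker <- fit_ranking_model(lists, split$train, vocab, rank_cfg,
                                features = feats_train, verbose = verbose)
  }
  # stage 6: evaluation on the test subset
  rxn_log("stage evaluate (%d test entries)", length(split$test),
          verbose = verbose)
  report <- evaluate_pipeline(split$test, cand, ranker, vocab, threshold,
                              ks = config$top_k_eval)
  report$threshold <- threshold
  out <- list(models = list(candidate = cand, ranking = ranker),
              threshold = threshold, report = report, split = split,
              vocab = vocab, truth = truth,
              elapsed_s = as.numeric(difftime(Sys.time(), t0, "secs")))
  if (!is.null(out_dir)) {
    write_vocabulary(vocab, file.path(out_dir, "vocabulary.tsv"))
    utils::write.table(split$manifest, file.path(out_dir, "split.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(report$recommendations)) {
      utils::write.table(report$recommendations,
                         file.path(out_dir, "recommendations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    report_json <- report[setdiff(names(report), "recommendations")]
    jsonlite::write_json(report_json, file.path(out_dir, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    manifest <- list(seed = config$seed, ratios = config$ratios,
                     threshold = threshold,
                     vocab_checksum = vocab$checksum,
                     n_entries = length(fl$entries),
                     elapsed_s = out$elapsed_s)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Evaluate a trained model pair on held-out entries
#'
#' Computes the example-based multi-label metrics at the given threshold,
#' the top-k exact-match hit rates, the multi-record top-20 table, and the
#' temperature metrics over recorded conditions reproduced in the
#' recommendations.
#'
#' @param entries held-out reaction entries.
#' @param candidate_model,ranking_model trained models; a `NULL`
#'   `ranking_model` limits the report to candidate metrics (stated in the
#'   report's `scope`).
#' @param vocab vocabulary.
#' @param threshold candidate cutoff.
#' @param ks top-k values.
#' @param enum_cap per-reaction enumeration cap; reactions whose candidate
#'   enumeration exceeds it are scored as misses rather than erroring.
#' @return list of evaluation tables.
#' @export
evaluate_pipeline <- function(entries, candidate_model, ranking_model,
                              vocab, threshold = 0.3, ks = c(1, 3, 10, 20),
                              enum_cap = 10000) {
  X <- entry_features(entries, candidate_model$config$radius,
                      candidate_model$config$nbits)
  probs <- predict(candidate_model, features = X)
  Y <- entry_targets(entries, vocab)
  to_sets <- function(M) apply(M, 1, function(r) which(r > 0.5),
                               simplify = FALSE)
  mm_r <- multilabel_metrics(to_sets(Y$reagent),
                             to_sets(probs$reagent >= threshold),
                             nrow(vocab$reagent))
  mm_s <- multilabel_metrics(to_sets(Y$solvent),
                             to_sets(probs$solvent >= threshold),
                             nrow(vocab$solvent))
  if (is.null(ranking_model)) {
    return(list(scope = "candidate metrics only (ranking stage disabled)",
                multilabel = list(reagent = mm_r, solvent = mm_s)))
  }
  recs <- vector("list", length(entries))
  temp_pred <- temp_true <- numeric(0)
  for (i in seq_along(entries)) {
    cands <- select_candidates(list(reagent = probs$reagent[i, ],
                                    solvent = probs$solvent[i, ]),
                               threshold)
    ranked <- tryCatch({
      contexts <- enumerate_contexts(cands, cap = enum_cap)
      rank_contexts(ranking_model, contexts = contexts,
                    fingerprint = X[i, ])
    }, error = function(e) {
      data.frame(rank = integer(0), reagents = character(0),
                 solvents = character(0), score = numeric(0),
                 temperature_c = numeric(0), stringsAsFactors = FALSE)
    })
    recs[[i]] <- ranked
    if (nrow(ranked)) {
      keys <- ranked_context_keys(ranked)
      for (cond in entries[[i]]$conditions) {
        if (is.na(cond$temperature)) next
        j <- match(context_key(cond$reagents, cond$solvents), keys)
        if (!is.na(j)) {
          temp_pred <- c(temp_pred, ranked$temperature_c[j])
          temp_true <- c(temp_true, cond$temperature)
        }
      }
    }
  }
  topk <- topk_exact_match(recs, entries, ks)
  multi <- multi_record_hits(recs, entries)
  temp <- if (length(temp_true) >= 2) {
    temperature_metrics(temp_pred, temp_true)
  } else NULL
  rec_df <- do.call(rbind, lapply(seq_along(entries), function(i) {
    if (nrow(recs[[i]]) == 0) return(NULL)
    cbind(reaction_id = entries[[i]]$reaction_id, recs[[i]],
          stringsAsFactors = FALSE)
  }))
  list(scope = "full",
       multilabel = list(reagent = mm_r, solvent = mm_s),
       topk = list(hit_rates = as.list(topk$hit_rates), n = topk$n),
       multi_record = list(table = multi$table,
                           bucket_sizes = multi$bucket_sizes),
       temperature = temp,
       recommendations = rec_df)
}

#' Save / load a trained model pair
#'
#' Checkpoints carry the vocabulary checksum; loading against a different
#' vocabulary is refused.
#' @param model an `rxn_candidate_model` or `rxn_ranking_model`.
#' @param path file path (RDS).
#' @export
save_model <- function(model, path) {
  saveRDS(list(model = model, vocab_checksum = model$vocab$checksum), path)
  invisible(path)
}

#' @rdname save_model
#' @param vocab vocabulary the checkpoint must match (`NULL` skips the
#'   check).
#' @export
load_model <- function(path, vocab = NULL) {
  obj <- readRDS(path)
  if (!is.null(vocab) && !identical(obj$vocab_checksum, vocab$checksum)) {
    stop("checkpoint was trained against a different vocabulary",
         call. = FALSE)
  }
  obj$model
}
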