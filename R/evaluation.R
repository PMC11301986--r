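# Evaluation protocols: example-based multi-label metrics, top-k exact-match
# hit rates, the multi-record top-20 table, temperature accuracy, and
# embedding extraction from the candidate network.

#' Example-based multi-label metrics
#'
#' Hamming loss, precision, recall and F1, averaged over instances:
#' hamming is the mean of `|Z xor Y| / q`; precision is the mean of
#' `|Y n Z| / |Z|` (defined as 0 when `|Z| = 0`); recall the mean of
#' `|Y n Z| / |Y|`; F1 the mean of `2|Y n Z| / (|Y| + |Z|)`. The aggregate
#' identity `F1 = 2PR/(P+R)` holds per instance but not for these averages,
#' and is not used.
#'
#' @param true_sets,pred_sets lists of label vectors (or integer index
#'   vectors), one element per instance.
#' @param q number of labels in the class.
#' @return list with `hamming`, `precision`, `recall`, `f1`.
#' @export
multilabel_metrics <- function(true_sets, pred_sets, q) {
  if (q <= 0) stop("q must be positive", call. = FALSE)
  n <- length(true_sets)
  if (n == 0 || n != length(pred_sets)) {
    stop("need equal, non-zero numbers of true and predicted sets",
         call. = FALSE)
  }
  ham <- prec <- rec <- f1 <- numeric(n)
  for (i in seq_len(n)) {
    Y <- unique(true_sets[[i]]); Z <- unique(pred_sets[[i]])
    inter <- length(intersect(Y, Z))
    sym <- length(Y) + length(Z) - 2 * inter
    ham[i] <- sym / q
    prec[i] <- if (length(Z) == 0) 0 else inter / length(Z)
    rec[i] <- if (length(Y) == 0) 0 else inter / length(Y)
    f1[i] <- if (length(Y) + length(Z) == 0) 0 else
      2 * inter / (length(Y) + length(Z))
  }
  list(hamming = mean(ham), precision = mean(prec), recall = mean(rec),
       f1 = mean(f1))
}

context_key <- function(reagents, solvents) {
  paste(set_key(reagents), set_key(solvents), sep = "\x02")
}

ranked_context_keys <- function(ranked) {
  vapply(seq_len(nrow(ranked)), function(i) {
    context_key(split_labels(ranked$reagents[i]),
                split_labels(ranked$solvents[i]))
  }, character(1))
}

record_keys <- function(entry) {
  vapply(entry$conditions, function(cond) {
    context_key(cond$reagents, cond$solvents)
  }, character(1))
}

#' Top-k exact-match hit rates
#'
#' A reaction counts as a hit at `k` when any of its recorded
#' (reagent set, solvent set) pairs equals any of the top-`k` recommended
#' pairs; equality is set equality on both roles, temperature is ignored.
#'
#' @param recommendations list of ranked data frames (one per reaction, as
#'   from [rank_contexts()]).
#' @param entries the matching reaction entries (same order).
#' @param ks the k values to report (default 1, 3, 10, 20).
#' @return list with `hit_rates` (named numeric), `n` reactions evaluated.
#' @export
topk_exact_match <- function(recommendations, entries,
                             ks = c(1, 3, 10, 20)) {
  stopifnot(length(recommendations) == length(entries))
  n <- length(entries)
  hits <- matrix(FALSE, n, length(ks))
  for (i in seq_len(n)) {
    rk <- ranked_context_keys(recommendations[[i]])
    rec <- record_keys(entries[[i]])
    first <- match(TRUE, rk %in% rec)
    if (!is.na(first)) hits[i, ] <- first <= ks
  }
  rates <- colMeans(hits)
  names(rates) <- paste0("top", ks)
  list(hit_rates = rates, n = n)
}

#' Multi-record hit table (top-20 protocol)
#'
#' Buckets reactions by their number of condition records (1 to
#' `max_records`) and reports, for each bucket `r` and each `j <= r`, the
#' fraction of reactions with at least `j` of their records present among
#' the top-`k` recommendations.
#'
#' @inheritParams topk_exact_match
#' @param k recommendation window (default 20).
#' @param max_records largest bucket (default 5).
#' @return list with `table` (matrix, rows = record-count buckets, columns =
#'   minimum hit counts) and `bucket_sizes`.
#' @export
multi_record_hits <- function(recommendations, entries, k = 20,
                              max_records = 5) {
  stopifnot(length(recommendations) == length(entries))
  tab <- matrix(NA_real_, max_records, max_records,
                dimnames = list(records = seq_len(max_records),
                                min_hits = seq_len(max_records)))
  sizes <- integer(max_records)
  n_rec <- vapply(entries, function(e) length(e$conditions), integer(1))
  n_hit <- integer(length(entries))
  for (i in seq_along(entries)) {
    topk <- utils::head(ranked_context_keys(recommendations[[i]]), k)
    n_hit[i] <- sum(record_keys(entries[[i]]) %in% topk)
  }
  for (r in seq_len(max_records)) {
    in_bucket <- which(n_rec == r)
    sizes[r] <- length(in_bucket)
    if (length(in_bucket) == 0) next
    for (j in seq_len(r)) {
      tab[r, j] <- mean(n_hit[in_bucket] >= j)
    }
  }
  list(table = tab, bucket_sizes = sizes, k = k)
}

#' Temperature prediction accuracy
#'
#' Mean absolute error, the fractions of predictions within 10 and 20
#' degrees Celsius of the truth, and the MAEs of constant baselines that
#' always predict the mean or the median of a reference temperature
#' distribution (the truths themselves by default).
#'
#' @param predictions,truths aligned numeric vectors in degrees Celsius.
#' @param reference temperature distribution for the baselines (defaults to
#'   `truths`).
#' @return list with `mae`, `within_10`, `within_20`, `baseline_mean_mae`,
#'   `baseline_median_mae`, `n`.
#' @export
temperature_metrics <- function(predictions, truths, reference = truths) {
  if (length(predictions) != length(truths) || length(truths) == 0) {
    stop("predictions and truths must be aligned and non-empty",
         call. = FALSE)
  }
  err <- abs(predictions - truths)
  list(mae = mean(err),
       within_10 = mean(err <= 10),
       within_20 = mean(err <= 20),
       baseline_mean_mae = mean(abs(mean(reference) - truths)),
       baseline_median_mae = mean(abs(stats::median(reference) - truths)),
       n = length(truths))
}

#' Correlation between predicted scores and latent yields
#'
#' Benchmark protocol for synthetic worlds: for every reaction, the ranking
#' model scores each condition in its template's compatibility table; the
#' per-reaction Spearman correlation between predicted score and latent
#' yield is averaged over reactions whose tables hold at least
#' `min_conditions` distinct yields.
#'
#' @param model an `rxn_ranking_model`.
#' @param entries held-out reaction entries.
#' @param truth the hidden truth from [sample_dataset()].
#' @param min_conditions minimum conditions per reaction (default 3).
#' @param features optional precomputed feature matrix for `entries`.
#' @return list with `mean_spearman`, `per_reaction` (numeric vector), `n`.
#' @export
yield_rank_correlation <- function(model, entries, truth,
                                   min_conditions = 3, features = NULL) {
  fp <- features %||%
    entry_features(entries, model$config$radius, model$config$nbits)
  cond_tab <- truth$conditions
  rho <- rep(NA_real_, length(entries))
  for (i in seq_along(entries)) {
    t <- truth$template[entries[[i]]$reaction_id]
    sub <- cond_tab[cond_tab$template == t, ]
    if (nrow(sub) < min_conditions) next
    contexts <- lapply(seq_len(nrow(sub)), function(j)
      list(reagents = split_labels(sub$reagents[j]),
           solvents = split_labels(sub$solvents[j])))
    ranked <- rank_contexts(model, contexts = contexts,
                            fingerprint = fp[i, ])
    # map ranked rows back to the condition table rows
    key_rank <- ranked_context_keys(ranked)
    key_tab <- vapply(contexts, function(cx)
      context_key(cx$reagents, cx$solvents), character(1))
    score <- ranked$score[match(key_tab, key_rank)]
    if (stats::sd(sub$latent_yield) == 0 || stats::sd(score) == 0) next
    rho[i] <- stats::cor(score, sub$latent_yield, method = "spearman")
  }
  ok <- !is.na(rho)
  list(mean_spearman = mean(rho[ok]), per_reaction = rho, n = sum(ok))
}

#' Extract hidden-layer embeddings from the candidate model
#'
#' Returns the activations of the shared layer or of one of the
#' task-specific layers, one row per reaction; identical reactions give
#' identical rows.
#'
#' @param model an `rxn_candidate_model`.
#' @param entries reaction entries.
#' @param layer `"shared"`, `"reagent_task"` or `"solvent_task"`.
#' @param features optional precomputed feature matrix.
#' @return numeric matrix with reaction ids as row names.
#' @export
extract_embeddings <- function(model, entries,
                               layer = c("shared", "reagent_task",
                                         "solvent_task"),
                               features = NULL) {
  layer <- match.arg(layer)
  X <- features %||%
    entry_features(entries, model$config$radius, model$config$nbits)
  fw <- cand_forward(model$params, X)
  M <- switch(layer, shared = fw$H1, reagent_task = fw$Hr,
              solvent_task = fw$Hs)
  rownames(M) <- rownames(X)
  M
}

#' Write an embedding matrix as delimited text
#'
#' @param M matrix from [extract_embeddings()].
#' @param path output TSV (header row; first column `reaction_id`).
#' @param tags optional character vector of reaction-type tags.
#' @export
write_embeddings <- function(M, path, tags = NULL) {
  df <- data.frame(reaction_id = rownames(M), stringsAsFactors = FALSE)
  if (!is.null(tags)) df$tag <- tags
  df <- cbind(df, as.data.frame(M))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
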