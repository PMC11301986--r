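# Hard negative sampling: augment each reaction's recorded conditions with
# plausible-looking wrong labels (high predicted probability, never recorded)
# and enumerate the combined label pool into a training list with
# yield-derived relevance targets.

#' Yield-derived relevance score
#'
#' `s = 2 * yield + 2` for a recorded context (yield as a fraction), so
#' recorded conditions score in `[2, 4]`; any context not matching a record
#' scores 0.
#'
#' @param yield fraction in `[0,1]`, or `NA`/`NULL` for an unrecorded context.
#' @return numeric score.
#' @export
#' @examples
#' relevance_score(0.97)  # 3.94
#' relevance_score(NULL)  # 0
relevance_score <- function(yield) {
  if (is.null(yield) || length(yield) == 0 || all(is.na(yield))) return(0)
  if (any(yield < 0 | yield > 1)) {
    stop("yield must be a fraction in [0,1]", call. = FALSE)
  }
  2 * yield + 2
}

#' Mine hard negative labels
#'
#' Labels the candidate model scores strictly above `cutoff` but that never
#' appear in the reaction's recorded conditions. At most `cap` labels per
#' task are kept (the most probable ones).
#'
#' @param probs list of named probability vectors `reagent`, `solvent` for
#'   one reaction.
#' @param positives list of character vectors `reagent`, `solvent`: the union
#'   of recorded labels.
#' @param cutoff probability cutoff (strict, default 0.1).
#' @param cap per-task cap on mined labels (default 5).
#' @return list of character vectors `reagent`, `solvent`.
#' @export
hard_negative_labels <- function(probs, positives, cutoff = 0.1, cap = 5) {
  one <- function(p, pos) {
    cand <- names(p)[p > cutoff & !(names(p) %in% pos)]
    if (length(cand) > cap) {
      cand <- cand[order(-p[cand], method = "radix")][seq_len(cap)]
    }
    cand[order(-p[cand], method = "radix")]
  }
  list(reagent = one(probs$reagent, positives$reagent),
       solvent = one(probs$solvent, positives$solvent))
}

entry_positive_labels <- function(entry) {
  list(reagent = unique(unlist(lapply(entry$conditions, `[[`, "reagents"))),
       solvent = unique(unlist(lapply(entry$conditions, `[[`, "solvents"))))
}

#' Build the augmented training list of one reaction
#'
#' Pools the reaction's recorded (positive) labels with its mined hard
#' negatives, enumerates all reaction contexts over the pool (subset caps as
#' in [enumerate_contexts()]), and aligns relevance and temperature targets:
#' a context whose reagent and solvent sets both exactly equal a recorded
#' condition receives that record's `2*yield + 2` relevance and temperature;
#' every other context receives relevance 0 and no temperature target.
#'
#' @param entry one reaction entry (>= 1 condition record).
#' @param probs per-task named probability vectors for this reaction (from
#'   the trained candidate model); `NULL` disables augmentation.
#' @param cutoff,cap hard-negative mining parameters
#'   (see [hard_negative_labels()]).
#' @param max_reagents,max_solvents,enum_cap enumeration parameters.
#' @return a list of class `training_list`: `reaction_id`, `contexts`,
#'   `relevance`, `temperature` (NA where untargeted), `n`.
#' @export
build_training_list <- function(entry, probs = NULL, cutoff = 0.1, cap = 5,
                                max_reagents = 3, max_solvents = 2,
                                enum_cap = 10000) {
  pos <- entry_positive_labels(entry)
  neg <- if (is.null(probs)) list(reagent = character(0),
                                  solvent = character(0))
         else hard_negative_labels(probs, pos, cutoff, cap)
  pool <- list(reagents = c(pos$reagent, neg$reagent),
               solvents = c(pos$solvent, neg$solvent))
  contexts <- enumerate_contexts(pool, max_reagents, max_solvents, enum_cap)
  rec_keys <- vapply(entry$conditions, function(cond) {
    paste(set_key(cond$reagents), set_key(cond$solvents), sep = "\x02")
  }, character(1))
  relevance <- numeric(length(contexts))
  temperature <- rep(NA_real_, length(contexts))
  for (i in seq_along(contexts)) {
    key <- paste(set_key(contexts[[i]]$reagents),
                 set_key(contexts[[i]]$solvents), sep = "\x02")
    j <- match(key, rec_keys)
    if (!is.na(j)) {
      relevance[i] <- relevance_score(entry$conditions[[j]]$yield)
      temperature[i] <- entry$conditions[[j]]$temperature
    }
  }
  structure(list(reaction_id = entry$reaction_id, contexts = contexts,
                 relevance = relevance, temperature = temperature,
                 n = length(contexts)),
            class = "training_list")
}

#' Build training lists for many entries
#'
#' @param entries list of reaction entries.
#' @param model trained `rxn_candidate_model` used to mine hard negatives
#'   (`NULL` disables augmentation).
#' @param features optional precomputed feature matrix for `entries`.
#' @inheritParams build_training_list
#' @return list of `training_list` objects (entries whose enumeration
#'   exceeds `enum_cap` raise an error).
#' @export
build_training_lists <- function(entries, model = NULL, features = NULL,
                                 cutoff = 0.1, cap = 5, max_reagents = 3,
                                 max_solvents = 2, enum_cap = 10000) {
  probs_all <- if (!is.null(model)) {
    predict(model, entries, features = features)
  } else NULL
  lapply(seq_along(entries), function(i) {
    probs <- if (!is.null(probs_all)) {
      list(reagent = probs_all$reagent[i, ], solvent = probs_all$solvent[i, ])
    } else NULL
    build_training_list(entries[[i]], probs, cutoff, cap,
                        max_reagents, max_solvents, enum_cap)
  })
}

#' Serialize training lists as JSON lines
#'
#' One JSON object per line: reaction id, contexts as label arrays,
#' relevance, temperature (null where masked).
#' @param lists list of `training_list` objects.
#' @param path output file.
#' @export
write_training_lists <- function(lists, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (tl in lists) {
    obj <- list(reaction_id = tl$reaction_id,
                contexts = lapply(tl$contexts, function(cx)
                  list(reagents = cx$reagents, solvents = cx$solvents)),
                relevance = tl$relevance,
                temperature = tl$temperature)
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, na = "null",
                                digits = NA), con)
  }
  invisible(path)
}
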