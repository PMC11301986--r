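# Listwise ranking model: scores every enumerated reaction context and
# predicts its temperature. Inputs are the reaction fingerprint plus
# multi-hot reagent and solvent vectors; the two input branches pass through
# separate dense layers, concatenate, and feed a trunk with two scalar
# heads. Training minimizes the per-list KL ranking loss plus the masked MSE
# temperature loss, combined with learned homoscedastic weights.

#' Configuration for the ranking model
#'
#' @param radius,nbits fingerprint parameters (must match the features used
#'   for candidate generation).
#' @param fp_hidden width of the fingerprint branch.
#' @param cond_hidden width of the condition (multi-hot) branch.
#' @param trunk_hidden width of the shared trunk layer.
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param batch_lists training lists per minibatch (lists are whole units;
#'   contexts of one list are never split across batches).
#' @param loss_variant homoscedastic weighting form, as in
#'   [candidate_config()].
#' @param kl_direction `"target_first"` for `KL(P_target || P_pred)`
#'   (ListNet convention) or `"pred_first"` for the reverse.
#' @param seed integer seed.
#' @return a list of class `ranking_config`.
#' @export
ranking_config <- function(radius = 2, nbits = 4096, fp_hidden = 512,
                           cond_hidden = 128, trunk_hidden = 256,
                           lr = 1e-3, epochs = 30, batch_lists = 16,
                           loss_variant = c("sigma", "sigma2"),
                           kl_direction = c("target_first", "pred_first"),
                           seed = 1) {
  loss_variant <- match.arg(loss_variant)
  kl_direction <- match.arg(kl_direction)
  stopifnot(fp_hidden > 0, cond_hidden > 0, trunk_hidden > 0,
            epochs > 0, batch_lists > 0)
  structure(list(radius = radius, nbits = nbits, fp_hidden = fp_hidden,
                 cond_hidden = cond_hidden, trunk_hidden = trunk_hidden,
                 lr = lr, epochs = epochs, batch_lists = batch_lists,
                 loss_variant = loss_variant, kl_direction = kl_direction,
                 seed = seed),
            class = "ranking_config")
}

rank_init_params <- function(d_fp, d_cond, config) {
  with_seed(config$seed, {
    hf <- config$fp_hidden; hc <- config$cond_hidden
    ht <- config$trunk_hidden
    list(Wf = glorot(d_fp, hf), bf = numeric(hf),
         Wc = glorot(d_cond, hc), bc = numeric(hc),
         Wt = glorot(hf + hc, ht), bt = numeric(ht),
         ws = glorot(ht, 1), bs = 0,
         wz = glorot(ht, 1), bz = 0,
         a_rank = 0, a_temp = 0)
  })
}

rank_forward <- function(params, Xf, Xc) {
  Hf <- relu(add_bias(Xf %*% params$Wf, params$bf))
  Hc <- relu(add_bias(Xc %*% params$Wc, params$bc))
  H <- cbind(Hf, Hc)
  Ht <- relu(add_bias(H %*% params$Wt, params$bt))
  list(Hf = Hf, Hc = Hc, Ht = Ht,
       score = drop(Ht %*% params$ws) + params$bs,
       temp = drop(Ht %*% params$wz) + params$bz)
}

# KL ranking loss and its gradient wrt predicted scores for one list.
list_kl <- function(pred, target, direction) {
  pt <- top_one_probability(target)
  pp <- top_one_probability(pred)
  if (direction == "target_first") {
    loss <- sum(pt * (log(pt) - log(pp)))
    grad <- pp - pt
  } else {
    loss <- sum(pp * (log(pp) - log(pt)))
    grad <- pp * ((log(pp) - log(pt)) - sum(pp * (log(pp) - log(pt))))
  }
  list(loss = loss, grad = grad)
}

rank_batch_grads <- function(params, Xf, Xc, groups, relevance, temp_target,
                             config) {
  fw <- rank_forward(params, Xf, Xc)
  n_lists <- length(groups)
  dscore <- numeric(nrow(Xf))
  loss_rank <- 0
  for (g in groups) {
    kl <- list_kl(fw$score[g], relevance[g], config$kl_direction)
    loss_rank <- loss_rank + kl$loss / n_lists
    dscore[g] <- kl$grad / n_lists
  }
  mask <- !is.na(temp_target)
  n_m <- sum(mask)
  if (n_m > 0) {
    resid <- fw$temp[mask] - temp_target[mask]
    loss_temp <- mean(resid^2)
    dtemp <- numeric(nrow(Xf))
    dtemp[mask] <- 2 * resid / n_m
  } else {
    loss_temp <- 0
    dtemp <- numeric(nrow(Xf))
  }
  s_rank <- exp(params$a_rank); s_temp <- exp(params$a_temp)
  w_rank <- multitask_weight(s_rank, config$loss_variant)
  w_temp <- multitask_weight(s_temp, config$loss_variant)
  total <- combined_multitask_loss(loss_rank, loss_temp, s_rank, s_temp,
                                   config$loss_variant)
  dscore <- dscore * w_rank
  dtemp <- dtemp * w_temp

  dHt <- (outer(dscore, drop(params$ws)) + outer(dtemp, drop(params$wz))) *
    (fw$Ht > 0)
  dH <- dHt %*% t(params$Wt)
  hf <- config$fp_hidden
  dHf <- dH[, seq_len(hf), drop = FALSE] * (fw$Hf > 0)
  dHc <- dH[, -seq_len(hf), drop = FALSE] * (fw$Hc > 0)
  grads <- list(
    Wf = t(Xf) %*% dHf, bf = colSums(dHf),
    Wc = t(Xc) %*% dHc, bc = colSums(dHc),
    Wt = t(cbind(fw$Hf, fw$Hc)) %*% dHt, bt = colSums(dHt),
    ws = matrix(colSums(fw$Ht * dscore), ncol = 1), bs = sum(dscore),
    wz = matrix(colSums(fw$Ht * dtemp), ncol = 1), bz = sum(dtemp),
    a_rank = multitask_logsigma_grad(loss_rank, s_rank, config$loss_variant),
    a_temp = if (n_m > 0) {
      multitask_logsigma_grad(loss_temp, s_temp, config$loss_variant)
    } else 0)
  list(grads = grads, loss = total, loss_rank = loss_rank,
       loss_temp = loss_temp)
}

# Stack the rows of many training lists into matrices plus group indices.
rank_design <- function(lists, entry_fp, vocab) {
  n_rows <- sum(vapply(lists, function(l) l$n, numeric(1)))
  d_fp <- ncol(entry_fp)
  Vr <- nrow(vocab$reagent); Vs <- nrow(vocab$solvent)
  Xf <- matrix(0, n_rows, d_fp)
  Xc <- matrix(0, n_rows, Vr + Vs)
  relevance <- numeric(n_rows)
  temp <- rep(NA_real_, n_rows)
  groups <- vector("list", length(lists))
  row <- 0
  for (k in seq_along(lists)) {
    tl <- lists[[k]]
    idx <- row + seq_len(tl$n)
    Xf[idx, ] <- matrix(entry_fp[tl$reaction_id, ], tl$n, d_fp, byrow = TRUE)
    for (i in seq_len(tl$n)) {
      cx <- tl$contexts[[i]]
      ri <- match(cx$reagents, vocab$reagent$label)
      si <- match(cx$solvents, vocab$solvent$label)
      if (anyNA(ri) || anyNA(si)) {
        stop("context label outside vocabulary (reaction ",
             tl$reaction_id, ")", call. = FALSE)
      }
      Xc[idx[i], ri] <- 1
      Xc[idx[i], Vr + si] <- 1
    }
    relevance[idx] <- tl$relevance
    temp[idx] <- tl$temperature
    groups[[k]] <- idx
    row <- row + tl$n
  }
  list(Xf = Xf, Xc = Xc, relevance = relevance, temp = temp, groups = groups)
}

#' Fit the listwise ranking model
#'
#' @param lists training lists from [build_training_lists()].
#' @param entries the reaction entries the lists refer to (for fingerprints).
#' @param vocab label vocabulary.
#' @param config a [ranking_config()].
#' @param features optional precomputed feature matrix for `entries` (rows
#'   named by reaction id).
#' @param verbose print per-epoch progress.
#' @return an object of class `rxn_ranking_model` carrying the network
#'   parameters, the temperature normalization constants (train mean/sd) and
#'   the observed train temperature range.
#' @export
fit_ranking_model <- function(lists, entries, vocab,
                              config = ranking_config(), features = NULL,
                              verbose = FALSE) {
  if (length(lists) == 0) stop("no training lists", call. = FALSE)
  fp <- features %||% entry_features(entries, config$radius, config$nbits)
  des <- rank_design(lists, fp, vocab)
  temps <- des$temp[!is.na(des$temp)]
  t_mean <- if (length(temps)) mean(temps) else 0
  t_sd <- if (length(temps) > 1 && stats::sd(temps) > 0) stats::sd(temps)
          else 1
  t_range <- if (length(temps)) range(temps) else c(0, 0)
  temp_norm <- (des$temp - t_mean) / t_sd

  params <- rank_init_params(ncol(des$Xf), ncol(des$Xc), config)
  state <- adam_init(params)
  n_lists <- length(lists)
  history <- list()
  with_seed(config$seed + 1, {
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n_lists)
      starts <- seq(1, n_lists, by = config$batch_lists)
      ep <- c(loss = 0, rank = 0, temp = 0)
      for (s in starts) {
        lk <- perm[s:min(s + config$batch_lists - 1, n_lists)]
        rows <- unlist(des$groups[lk])
        remap <- integer(nrow(des$Xf)); remap[rows] <- seq_along(rows)
        groups <- lapply(des$groups[lk], function(g) remap[g])
        bg <- rank_batch_grads(params, des$Xf[rows, , drop = FALSE],
                               des$Xc[rows, , drop = FALSE], groups,
                               des$relevance[rows], temp_norm[rows], config)
        if (!is.finite(bg$loss)) {
          stop("divergent loss at epoch ", epoch, call. = FALSE)
        }
        st <- adam_step(params, bg$grads, state, lr = config$lr)
        params <- st$params; state <- st$state
        w <- length(lk) / n_lists
        ep <- ep + c(bg$loss, bg$loss_rank, bg$loss_temp) * w
      }
      history[[epoch]] <- data.frame(epoch = epoch, loss = unname(ep[1]),
                                     loss_rank = unname(ep[2]),
                                     loss_temp = unname(ep[3]))
      if (verbose) {
        rxn_log("epoch %d  loss %.4f (rank %.4f, temp %.4f)",
                epoch, ep[1], ep[2], ep[3])
      }
    }
  })
  structure(list(params = params, config = config, vocab = vocab,
                 temp_mean = t_mean, temp_sd = t_sd, temp_range = t_range,
                 history = do.call(rbind, history),
                 sigma = c(rank = exp(params$a_rank),
                           temp = exp(params$a_temp))),
            class = "rxn_ranking_model")
}

#' @export
print.rxn_ranking_model <- function(x, ...) {
  cat("Listwise ranking model\n")
  cat(sprintf("  branches: fingerprint %d -> %d, conditions %d -> %d; trunk %d\n",
              2 * x$config$nbits, x$config$fp_hidden,
              nrow(x$vocab$reagent) + nrow(x$vocab$solvent),
              x$config$cond_hidden, x$config$trunk_hidden))
  cat(sprintf("  temperature normalization: mean %.1f C, sd %.1f C\n",
              x$temp_mean, x$temp_sd))
  cat(sprintf("  trained %d epochs, final loss %.4f, sigma rank/temp %.3f/%.3f\n",
              nrow(x$history), x$history$loss[nrow(x$history)],
              x$sigma[1], x$sigma[2]))
  invisible(x)
}

#' @export
summary.rxn_ranking_model <- function(object, ...) {
  print(object)
  cat("\nTraining history (last 5 epochs):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object)
}

#' Score and rank reaction contexts
#'
#' Runs the ranking network on every context, de-normalizes the temperature
#' head to degrees Celsius (clamped to the training range widened by 50
#' degrees as a sanity bound), and sorts stably by decreasing score, so ties
#' keep enumeration order.
#'
#' @param model an `rxn_ranking_model`.
#' @param entry one reaction entry (or pass `fingerprint`).
#' @param contexts list of contexts (`list(reagents=, solvents=)`).
#' @param fingerprint optional precomputed reaction fingerprint.
#' @return data frame with columns `rank`, `reagents`, `solvents` (';'
#'   joined), `score`, `temperature_c`.
#' @export
rank_contexts <- function(model, entry = NULL, contexts, fingerprint = NULL) {
  if (length(contexts) == 0) stop("no contexts to rank", call. = FALSE)
  fp <- fingerprint %||%
    reaction_fingerprint(entry$reactants, entry$products,
                         model$config$radius, model$config$nbits)
  tl <- list(reaction_id = "query", contexts = contexts,
             relevance = numeric(length(contexts)),
             temperature = rep(NA_real_, length(contexts)),
             n = length(contexts))
  fpm <- matrix(fp, 1, length(fp), dimnames = list("query", NULL))
  des <- rank_design(list(tl), fpm, model$vocab)
  fw <- rank_forward(model$params, des$Xf, des$Xc)
  temp_c <- clamp(fw$temp * model$temp_sd + model$temp_mean,
                  model$temp_range[1] - 50, model$temp_range[2] + 50)
  ord <- order(-fw$score)   # order() is stable: ties keep enumeration order
  data.frame(
    rank = seq_along(contexts),
    reagents = vapply(contexts[ord], function(cx)
      paste(cx$reagents, collapse = ";"), character(1)),
    solvents = vapply(contexts[ord], function(cx)
      paste(cx$solvents, collapse = ";"), character(1)),
    score = fw$score[ord],
    temperature_c = temp_c[ord],
    stringsAsFactors = FALSE)
}

#' Recommend ranked reaction conditions for one reaction
#'
#' End-to-end inference: candidate probabilities, thresholding (with argmax
#' fallback), combinatorial enumeration, then listwise ranking.
#'
#' @param entry a reaction entry (see [read_reaction_table()]).
#' @param candidate_model trained `rxn_candidate_model`.
#' @param ranking_model trained `rxn_ranking_model`.
#' @param threshold candidate probability cutoff.
#' @param top number of rows to return (Inf for all).
#' @param enum_cap enumeration cap.
#' @return ranked data frame as in [rank_contexts()].
#' @export
recommend_conditions <- function(entry, candidate_model, ranking_model,
                                 threshold = 0.3, top = 10,
                                 enum_cap = 10000) {
  probs <- predict(candidate_model, list(entry))
  cands <- select_candidates(list(reagent = probs$reagent[1, ],
                                  solvent = probs$solvent[1, ]), threshold)
  contexts <- enumerate_contexts(cands, cap = enum_cap)
  ranked <- rank_contexts(ranking_model, entry, contexts)
  utils::head(ranked, top)
}
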