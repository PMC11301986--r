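# Candidate generation: a multi-task multi-label network mapping the reaction
# difference fingerprint to independent per-label probabilities for reagents
# and solvents. Shared hidden layer + one task-specific hidden layer per
# task; focal loss per task, combined with learned homoscedastic weights.

#' Configuration for the candidate generation model
#'
#' @param radius,nbits fingerprint parameters (the network input has length
#'   `2 * nbits`).
#' @param hidden shared hidden layer width.
#' @param task_hidden width of each task-specific hidden layer.
#' @param dropout dropout rate on the shared hidden layer during training.
#' @param gamma focal-loss modulating factor (one value for both tasks or a
#'   length-2 vector `c(reagent, solvent)`).
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param batch minibatch size.
#' @param loss_variant `"sigma"` for the `1/(2*sigma)` homoscedastic weighting
#'   or `"sigma2"` for the `1/(2*sigma^2)` form.
#' @param threshold_grid candidate probability cutoffs scanned by
#'   [optimize_threshold()].
#' @param seed integer seed for initialization, shuffling and dropout.
#' @return a list of class `candidate_config`.
#' @export
candidate_config <- function(radius = 2, nbits = 4096, hidden = 1024,
                             task_hidden = 256, dropout = 0.3, gamma = 2,
                             lr = 1e-3, epochs = 30, batch = 128,
                             loss_variant = c("sigma", "sigma2"),
                             threshold_grid = seq(0.1, 0.7, by = 0.1),
                             seed = 1) {
  loss_variant <- match.arg(loss_variant)
  stopifnot(hidden > 0, task_hidden > 0, nbits > 0, epochs > 0, batch > 0,
            dropout >= 0, dropout < 1,
            all(threshold_grid > 0), all(threshold_grid < 1))
  if (any(gamma < 0)) stop("gamma must be non-negative", call. = FALSE)
  gamma <- rep(gamma, length.out = 2)
  structure(list(radius = radius, nbits = nbits, hidden = hidden,
                 task_hidden = task_hidden, dropout = dropout,
                 gamma_r = gamma[1], gamma_s = gamma[2], lr = lr,
                 epochs = epochs, batch = batch,
                 loss_variant = loss_variant,
                 threshold_grid = threshold_grid, seed = seed),
            class = "candidate_config")
}

cand_init_params <- function(d, config, q_r, q_s) {
  with_seed(config$seed, {
    h <- config$hidden; th <- config$task_hidden
    list(W1 = glorot(d, h), b1 = numeric(h),
         Wr1 = glorot(h, th), br1 = numeric(th),
         Wr2 = glorot(th, q_r), br2 = numeric(q_r),
         Ws1 = glorot(h, th), bs1 = numeric(th),
         Ws2 = glorot(th, q_s), bs2 = numeric(q_s),
         ar = 0, as = 0)   # log sigma_r, log sigma_s
  })
}

cand_forward <- function(params, X, drop_mask = NULL) {
  H1 <- relu(add_bias(X %*% params$W1, params$b1))
  if (!is.null(drop_mask)) H1 <- H1 * drop_mask
  Hr <- relu(add_bias(H1 %*% params$Wr1, params$br1))
  Hs <- relu(add_bias(H1 %*% params$Ws1, params$bs1))
  Zr <- add_bias(Hr %*% params$Wr2, params$br2)
  Zs <- add_bias(Hs %*% params$Ws2, params$bs2)
  list(H1 = H1, Hr = Hr, Hs = Hs, Pr = sigmoid(Zr), Ps = sigmoid(Zs))
}

cand_batch_grads <- function(params, X, Yr, Ys, config, drop_mask) {
  fw <- cand_forward(params, X, drop_mask)
  n <- nrow(X)
  loss_r <- mean(focal_loss(fw$Pr, Yr, config$gamma_r))
  loss_s <- mean(focal_loss(fw$Ps, Ys, config$gamma_s))
  sr <- exp(params$ar); ss <- exp(params$as)
  wr <- multitask_weight(sr, config$loss_variant)
  ws <- multitask_weight(ss, config$loss_variant)
  total <- combined_multitask_loss(loss_r, loss_s, sr, ss,
                                   config$loss_variant)

  dZr <- wr * focal_loss_grad(fw$Pr, Yr, config$gamma_r) *
    fw$Pr * (1 - fw$Pr) / length(Yr)
  dZs <- ws * focal_loss_grad(fw$Ps, Ys, config$gamma_s) *
    fw$Ps * (1 - fw$Ps) / length(Ys)

  dHr <- (dZr %*% t(params$Wr2)) * (fw$Hr > 0)
  dHs <- (dZs %*% t(params$Ws2)) * (fw$Hs > 0)
  dH1 <- dHr %*% t(params$Wr1) + dHs %*% t(params$Ws1)
  if (!is.null(drop_mask)) dH1 <- dH1 * drop_mask
  dH1 <- dH1 * (fw$H1 > 0)

  grads <- list(
    W1 = t(X) %*% dH1, b1 = colSums(dH1),
    Wr1 = t(fw$H1) %*% dHr, br1 = colSums(dHr),
    Wr2 = t(fw$Hr) %*% dZr, br2 = colSums(dZr),
    Ws1 = t(fw$H1) %*% dHs, bs1 = colSums(dHs),
    Ws2 = t(fw$Hs) %*% dZs, bs2 = colSums(dZs),
    ar = multitask_logsigma_grad(loss_r, sr, config$loss_variant),
    as = multitask_logsigma_grad(loss_s, ss, config$loss_variant))
  list(grads = grads, loss = total, loss_r = loss_r, loss_s = loss_s)
}

#' Fit the candidate generation model
#'
#' Trains the multi-label network on the union-of-records targets of the
#' training entries. Per-epoch training loss (and validation example-based F1
#' at threshold 0.3, when validation entries are given) is logged.
#'
#' @param train list of reaction entries (training subset).
#' @param vocab vocabulary from [build_vocabulary()].
#' @param config a [candidate_config()].
#' @param validation optional entry list for per-epoch monitoring.
#' @param verbose print per-epoch progress.
#' @return an object of class `rxn_candidate_model`.
#' @export
fit_candidate_model <- function(train, vocab, config = candidate_config(),
                                validation = NULL, verbose = FALSE) {
  if (length(train) == 0) stop("empty training set", call. = FALSE)
  X <- entry_features(train, config$radius, config$nbits)
  Y <- entry_targets(train, vocab)
  d <- ncol(X)
  params <- cand_init_params(d, config, ncol(Y$reagent), ncol(Y$solvent))
  state <- adam_init(params)
  n <- nrow(X)
  history <- list()
  Xv <- NULL
  if (!is.null(validation) && length(validation)) {
    Xv <- entry_features(validation, config$radius, config$nbits)
    Yv <- entry_targets(validation, vocab)
  }
  with_seed(config$seed + 1, {
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n)
      starts <- seq(1, n, by = config$batch)
      ep_loss <- 0; ep_r <- 0; ep_s <- 0
      for (s in starts) {
        idx <- perm[s:min(s + config$batch - 1, n)]
        drop_mask <- NULL
        if (config$dropout > 0) {
          drop_mask <- matrix(
            (stats::runif(length(idx) * config$hidden) >=
               config$dropout) / (1 - config$dropout),
            length(idx), config$hidden)
        }
        bg <- cand_batch_grads(params, X[idx, , drop = FALSE],
                               Y$reagent[idx, , drop = FALSE],
                               Y$solvent[idx, , drop = FALSE],
                               config, drop_mask)
        if (!is.finite(bg$loss)) {
          stop("divergent loss at epoch ", epoch, call. = FALSE)
        }
        st <- adam_step(params, bg$grads, state, lr = config$lr)
        params <- st$params; state <- st$state
        w <- length(idx) / n
        ep_loss <- ep_loss + bg$loss * w
        ep_r <- ep_r + bg$loss_r * w
        ep_s <- ep_s + bg$loss_s * w
      }
      rec <- list(epoch = epoch, loss = ep_loss, loss_r = ep_r, loss_s = ep_s)
      if (!is.null(Xv)) {
        fw <- cand_forward(params, Xv)
        rec$val_f1_reagent <- example_f1(fw$Pr >= 0.3, Yv$reagent)
        rec$val_f1_solvent <- example_f1(fw$Ps >= 0.3, Yv$solvent)
      }
      history[[epoch]] <- rec
      if (verbose) {
        rxn_log("epoch %d  loss %.4f (r %.4f, s %.4f)%s", epoch, ep_loss,
                ep_r, ep_s,
                if (!is.null(Xv)) sprintf("  val F1 r %.3f s %.3f",
                                          rec$val_f1_reagent,
                                          rec$val_f1_solvent) else "")
      }
    }
  })
  structure(list(params = params, config = config, vocab = vocab,
                 history = do.call(rbind, lapply(history, as.data.frame)),
                 sigma = c(reagent = exp(params$ar),
                           solvent = exp(params$as))),
            class = "rxn_candidate_model")
}

# mean example-based F1 from a binary prediction matrix
example_f1 <- function(Z, Y) {
  inter <- rowSums(Z & Y)
  denom <- rowSums(Z) + rowSums(Y)
  mean(ifelse(denom == 0, 1, 2 * inter / pmax(denom, 1)))
}

#' Predict label probabilities
#'
#' @param object an `rxn_candidate_model`.
#' @param entries list of reaction entries (or a precomputed feature matrix
#'   via `features`).
#' @param features optional feature matrix overriding `entries`.
#' @param ... unused.
#' @return list with matrices `reagent` and `solvent` (rows = reactions,
#'   columns = vocabulary labels, values in `[0,1]`).
#' @export
predict.rxn_candidate_model <- function(object, entries = NULL,
                                        features = NULL, ...) {
  X <- features %||%
    entry_features(entries, object$config$radius, object$config$nbits)
  fw <- cand_forward(object$params, X)
  colnames(fw$Pr) <- object$vocab$reagent$label
  colnames(fw$Ps) <- object$vocab$solvent$label
  list(reagent = fw$Pr, solvent = fw$Ps)
}

#' @export
print.rxn_candidate_model <- function(x, ...) {
  cat("Candidate generation model\n")
  cat(sprintf("  input: reaction fingerprint, %d dims (radius %d, %d bits)\n",
              2 * x$config$nbits, x$config$radius, x$config$nbits))
  cat(sprintf("  vocab: %d reagent labels, %d solvent labels\n",
              nrow(x$vocab$reagent), nrow(x$vocab$solvent)))
  cat(sprintf("  shared hidden %d, task hidden %d, dropout %.2f, gamma %.1f/%.1f\n",
              x$config$hidden, x$config$task_hidden, x$config$dropout,
              x$config$gamma_r, x$config$gamma_s))
  cat(sprintf("  trained %d epochs, final loss %.4f, sigma r/s %.3f/%.3f\n",
              nrow(x$history), x$history$loss[nrow(x$history)],
              x$sigma[1], x$sigma[2]))
  invisible(x)
}

#' @export
summary.rxn_candidate_model <- function(object, ...) {
  print(object)
  h <- object$history
  cat("\nTraining history (last 5 epochs):\n")
  print(utils::tail(h, 5), row.names = FALSE)
  if (!is.null(h$val_f1_reagent)) {
    cat(sprintf("\nbest validation F1 (threshold 0.3): reagent %.3f, solvent %.3f\n",
                max(h$val_f1_reagent), max(h$val_f1_solvent)))
  }
  invisible(object)
}

#' Threshold label probabilities into a candidate set
#'
#' Retains, per task, the labels with probability at or above the threshold,
#' sorted by decreasing probability. A task that retains nothing falls back
#' to its single most probable label and is flagged.
#'
#' @param probs list with named numeric vectors `reagent` and `solvent`
#'   (one reaction's probabilities), or a single row of the matrices from
#'   [predict.rxn_candidate_model()].
#' @param threshold probability cutoff (default 0.3).
#' @return a list of class `candidate_set`: per-task data frames
#'   (`label`, `prob`), counts `n_r`, `n_s`, the threshold, and fallback
#'   flags.
#' @export
select_candidates <- function(probs, threshold = 0.3) {
  one <- function(p) {
    keep <- which(p >= threshold)
    fallback <- FALSE
    if (length(keep) == 0) {
      keep <- which.max(p)
      fallback <- TRUE
    }
    ord <- keep[order(-p[keep], keep)]
    list(df = data.frame(label = names(p)[ord], prob = unname(p[ord]),
                         stringsAsFactors = FALSE),
         fallback = fallback)
  }
  r <- one(probs$reagent); s <- one(probs$solvent)
  structure(list(reagents = r$df, solvents = s$df,
                 n_r = nrow(r$df), n_s = nrow(s$df),
                 threshold = threshold,
                 fallback = c(reagent = r$fallback, solvent = s$fallback)),
            class = "candidate_set")
}

#' Select the probability threshold on validation data
#'
#' Scans a grid and returns the cutoff maximizing the mean of the reagent and
#' solvent example-based F1 scores on the validation entries; ties go to the
#' smallest threshold.
#'
#' @param model an `rxn_candidate_model`.
#' @param validation list of validation entries.
#' @param grid numeric vector of cutoffs (defaults to the model config grid).
#' @return list with `threshold` and the per-grid `scores` data frame.
#' @export
optimize_threshold <- function(model, validation,
                               grid = model$config$threshold_grid) {
  if (length(validation) == 0) stop("empty validation set", call. = FALSE)
  if (length(grid) == 0) stop("empty threshold grid", call. = FALSE)
  probs <- predict(model, validation)
  Y <- entry_targets(validation, model$vocab)
  grid <- sort(grid)
  f1 <- vapply(grid, function(t) {
    (example_f1(probs$reagent >= t, Y$reagent) +
       example_f1(probs$solvent >= t, Y$solvent)) / 2
  }, numeric(1))
  list(threshold = grid[which.max(f1)],   # which.max takes the first (smallest) tie
       scores = data.frame(threshold = grid, mean_f1 = f1))
}

#' Closed-form context count
#'
#' Number of (reagent subset, solvent subset) combinations from `n_r` reagent
#' and `n_s` solvent candidates with subset sizes capped at `max_reagents`
#' and `max_solvents`:
#' `(sum_i C(n_r, i)) * (sum_j C(n_s, j))`, `i <= 3`, `j <= 2` by default.
#'
#' @param n_r,n_s candidate counts.
#' @param max_reagents,max_solvents subset size caps.
#' @return integer count.
#' @export
context_count <- function(n_r, n_s, max_reagents = 3, max_solvents = 2) {
  sum(choose(n_r, seq_len(min(max_reagents, n_r)))) *
    sum(choose(n_s, seq_len(min(max_solvents, n_s))))
}

# all subsets of x with sizes 1..k, ordered by size then by element index
subsets_upto <- function(x, k) {
  out <- list()
  for (size in seq_len(min(k, length(x)))) {
    cmb <- utils::combn(seq_along(x), size)
    for (j in seq_len(ncol(cmb))) out[[length(out) + 1]] <- x[cmb[, j]]
  }
  out
}

#' Enumerate reaction contexts from a candidate set
#'
#' Crosses every non-empty reagent subset (size `<= max_reagents`) with every
#' non-empty solvent subset (size `<= max_solvents`), in a deterministic
#' order (subset size, then candidate rank). The number of contexts equals
#' [context_count()].
#'
#' @param cands a `candidate_set` from [select_candidates()], or a list with
#'   character vectors `reagents` and `solvents`.
#' @param max_reagents,max_solvents subset size caps.
#' @param cap hard limit on the enumeration size (default 10000).
#' @return list of contexts, each `list(reagents=, solvents=)`.
#' @export
enumerate_contexts <- function(cands, max_reagents = 3, max_solvents = 2,
                               cap = 10000) {
  rl <- if (inherits(cands, "candidate_set")) cands$reagents$label
        else cands$reagents
  sl <- if (inherits(cands, "candidate_set")) cands$solvents$label
        else cands$solvents
  if (length(rl) < 1 || length(sl) < 1) {
    stop("need at least one reagent and one solvent candidate",
         call. = FALSE)
  }
  total <- context_count(length(rl), length(sl), max_reagents, max_solvents)
  if (total > cap) {
    stop(sprintf(paste0("enumeration of %d contexts exceeds the cap (%d); ",
                        "raise the probability threshold"), total, cap),
         call. = FALSE)
  }
  rs <- subsets_upto(rl, max_reagents)
  ss <- subsets_upto(sl, max_solvents)
  out <- vector("list", length(rs) * length(ss))
  k <- 0
  for (r in rs) for (s in ss) {
    k <- k + 1
    out[[k]] <- list(reagents = r, solvents = s)
  }
  out
}
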