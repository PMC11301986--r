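# Minimal dense-network machinery: Glorot initialization, bias-broadcast
# helpers, and an Adam optimizer over a named list of parameter arrays. Both
# networks in the package are small multilayer perceptrons trained by manual
# backpropagation on BLAS-backed matrix products.

glorot <- function(n_in, n_out) {
  s <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -s, s), n_in, n_out)
}

add_bias <- function(A, b) {
  A + rep(b, each = nrow(A))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Multi-hot encoding of label sets against a vocabulary data frame.
multi_hot <- function(label_sets, vocab_df) {
  M <- matrix(0, length(label_sets), nrow(vocab_df))
  if (nrow(vocab_df) == 0) return(M)
  for (i in seq_along(label_sets)) {
    idx <- match(label_sets[[i]], vocab_df$label)
    if (anyNA(idx)) {
      stop("label outside vocabulary: ",
           paste(label_sets[[i]][is.na(idx)], collapse = ", "),
           call. = FALSE)
    }
    M[i, idx] <- 1
  }
  M
}

# Union-of-records multi-label targets for a set of entries.
entry_targets <- function(entries, vocab) {
  reag <- lapply(entries, function(e)
    unique(unlist(lapply(e$conditions, `[[`, "reagents"))))
  solv <- lapply(entries, function(e)
    unique(unlist(lapply(e$conditions, `[[`, "solvents"))))
  list(reagent = multi_hot(reag, vocab$reagent),
       solvent = multi_hot(solv, vocab$solvent))
}
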