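# Candidate selection, threshold optimization, enumeration and training.

test_that("selection keeps labels at/above threshold, with argmax fallback", {
  probs <- list(reagent = c(R1 = 0.4, R2 = 0.25),
                solvent = c(S1 = 0.8, S2 = 0.35))
  cs <- select_candidates(probs, threshold = 0.3)
  expect_identical(cs$reagents$label, "R1")
  expect_identical(cs$solvents$label, c("S1", "S2"))
  expect_identical(cs$n_r, 1L)
  expect_false(any(cs$fallback))
  # all below threshold: argmax fallback, flagged
  cs2 <- select_candidates(list(reagent = c(R1 = 0.1, R2 = 0.2),
                                solvent = c(S1 = 0.9)), threshold = 0.3)
  expect_identical(cs2$reagents$label, "R2")
  expect_true(cs2$fallback["reagent"])
  expect_false(cs2$fallback["solvent"])
  # threshold 0 keeps everything
  cs3 <- select_candidates(probs, threshold = 0)
  expect_identical(cs3$n_r + cs3$n_s, 4L)
})

test_that("lowering the threshold never shrinks the candidate set", {
  set.seed(5)
  probs <- list(reagent = setNames(runif(20), paste0("R", 1:20)),
                solvent = setNames(runif(8), paste0("S", 1:8)))
  prev_r <- character(0); prev_s <- character(0)
  for (t in seq(0.9, 0.05, by = -0.05)) {
    cs <- select_candidates(probs, t)
    if (!cs$fallback["reagent"]) {
      expect_true(all(prev_r %in% cs$reagents$label))
      prev_r <- cs$reagents$label
    }
    if (!cs$fallback["solvent"]) {
      expect_true(all(prev_s %in% cs$solvents$label))
      prev_s <- cs$solvents$label
    }
  }
})

test_that("context counts match the closed form and a brute-force oracle", {
  expect_identical(context_count(2, 2), 9)
  expect_identical(context_count(1, 1), 1)
  expect_identical(context_count(3, 2), 21)
  brute <- function(nr, ns, mr = 3, ms = 2) {
    cnt_sub <- function(n, k) {
      # enumerate all non-empty subsets explicitly
      sum(vapply(seq_len(2^n) - 1, function(mask) {
        sz <- sum(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
        sz >= 1 && sz <= k
      }, logical(1)))
    }
    cnt_sub(nr, mr) * cnt_sub(ns, ms)
  }
  for (nr in 1:6) for (ns in 1:4) {
    expect_equal(context_count(nr, ns), brute(nr, ns))
    cands <- list(reagents = paste0("R", 1:nr),
                  solvents = paste0("S", 1:ns))
    expect_length(enumerate_contexts(cands), context_count(nr, ns))
  }
})

test_that("enumeration order is deterministic and subsets respect caps", {
  ctx <- enumerate_contexts(list(reagents = c("A", "B", "C", "D"),
                                 solvents = c("X", "Y")))
  expect_length(ctx, context_count(4, 2))
  expect_identical(ctx[[1]], list(reagents = "A", solvents = "X"))
  sizes_r <- vapply(ctx, function(cx) length(cx$reagents), numeric(1))
  expect_true(all(sizes_r <= 3))
  expect_true(all(diff(order(sizes_r)) != 0))  # grouped by size blocks
  # identical call gives identical order
  expect_identical(ctx, enumerate_contexts(list(
    reagents = c("A", "B", "C", "D"), solvents = c("X", "Y"))))
  expect_error(enumerate_contexts(list(reagents = paste0("R", 1:20),
                                       solvents = paste0("S", 1:4)),
                                  cap = 100), "cap")
  expect_error(enumerate_contexts(list(reagents = character(0),
                                       solvents = "S")), "at least one")
})

test_that("threshold optimization maximizes mean example F1, ties to smallest", {
  d <- small_data()
  m <- small_candidate()
  opt <- optimize_threshold(m, d$split$validation, grid = c(0.3))
  expect_identical(opt$threshold, 0.3)
  opt2 <- optimize_threshold(m, d$split$validation)
  expect_identical(opt2$scores$mean_f1[opt2$scores$threshold ==
                                         opt2$threshold],
                   max(opt2$scores$mean_f1))
  # exact tie (both cutoffs sit above every probability): smallest wins
  tie <- optimize_threshold(m, d$split$validation,
                            grid = c(0.999999, 0.999998))
  expect_identical(tie$threshold, 0.999998)
  expect_identical(tie$scores$mean_f1[1], tie$scores$mean_f1[2])
  expect_error(optimize_threshold(m, list()), "empty")
})

test_that("training is seeded-reproducible and learns a noiseless world", {
  d <- noiseless_data()
  cfg <- candidate_config(nbits = 256, hidden = 64, task_hidden = 24,
                          dropout = 0.1, epochs = 25, lr = 2e-3, seed = 99)
  m1 <- fit_candidate_model(d$split$train, d$vocab, cfg)
  m2 <- fit_candidate_model(d$split$train, d$vocab, cfg)
  expect_identical(m1$history$loss[1], m2$history$loss[1])
  expect_identical(m1$params$W1, m2$params$W1)
  probs <- predict(m1, d$split$test)
  Y <- rxncond:::entry_targets(d$split$test, d$vocab)
  f1r <- rxncond:::example_f1(probs$reagent >= 0.3, Y$reagent)
  f1s <- rxncond:::example_f1(probs$solvent >= 0.3, Y$solvent)
  expect_gt(f1r, 0.9)
  expect_gt(f1s, 0.9)
})

test_that("probability outputs have vocabulary shape and [0,1] range; zero weights give 0.5", {
  d <- small_data()
  m <- small_candidate()
  probs <- predict(m, d$split$test[1:3])
  expect_identical(dim(probs$reagent), c(3L, nrow(d$vocab$reagent)))
  expect_identical(dim(probs$solvent), c(3L, nrow(d$vocab$solvent)))
  expect_true(all(probs$reagent >= 0 & probs$reagent <= 1))
  m0 <- m
  m0$params$Wr2[] <- 0; m0$params$br2[] <- 0
  m0$params$Ws2[] <- 0; m0$params$bs2[] <- 0
  p0 <- predict(m0, d$split$test[1])
  expect_true(all(p0$reagent == 0.5))
  expect_true(all(p0$solvent == 0.5))
  expect_error(fit_candidate_model(list(), d$vocab), "empty")
})
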