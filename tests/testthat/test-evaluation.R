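# Multi-label metrics, exact-match protocols, temperature report, embeddings.

ranked_df <- function(pairs) {
  data.frame(rank = seq_along(pairs),
             reagents = vapply(pairs, function(p)
               paste(p[[1]], collapse = ";"), character(1)),
             solvents = vapply(pairs, function(p)
               paste(p[[2]], collapse = ";"), character(1)),
             score = rev(seq_along(pairs)),
             temperature_c = 25, stringsAsFactors = FALSE)
}

entry_with_records <- function(id, records) {
  list(reaction_id = id, reaction_smiles = "CC=O>>CCO",
       reactants = "CC=O", products = "CCO",
       conditions = lapply(records, function(p)
         list(reagents = p[[1]], solvents = p[[2]],
              temperature = 25, yield = 0.8)))
}

test_that("example-based metrics match hand-worked values", {
  # perfect prediction
  mm <- multilabel_metrics(list(c("a", "b")), list(c("b", "a")), q = 4)
  expect_equal(unlist(mm), c(hamming = 0, precision = 1, recall = 1, f1 = 1))
  # q=4, Y={a}, Z={a,b}
  mm2 <- multilabel_metrics(list("a"), list(c("a", "b")), q = 4)
  expect_equal(mm2$hamming, 0.25)
  expect_equal(mm2$precision, 0.5)
  expect_equal(mm2$recall, 1.0)
  expect_equal(mm2$f1, 0.666667, tolerance = 1e-6)
  # empty prediction
  mm3 <- multilabel_metrics(list("a"), list(character(0)), q = 4)
  expect_equal(unlist(mm3),
               c(hamming = 0.25, precision = 0, recall = 0, f1 = 0))
  expect_error(multilabel_metrics(list("a"), list("a"), q = 0), "q")
})

test_that("metrics agree with a set-arithmetic brute-force oracle on fuzzed inputs", {
  oracle <- function(Y, Z, q) {
    h <- p <- r <- f <- numeric(length(Y))
    for (i in seq_along(Y)) {
      y <- Y[[i]]; z <- Z[[i]]
      inter <- sum(z %in% y)
      h[i] <- (length(setdiff(y, z)) + length(setdiff(z, y))) / q
      p[i] <- if (length(z)) inter / length(z) else 0
      r[i] <- if (length(y)) inter / length(y) else 0
      f[i] <- if (length(y) + length(z)) 2 * inter / (length(y) + length(z))
              else 0
    }
    c(mean(h), mean(p), mean(r), mean(f))
  }
  set.seed(31)
  for (rep in 1:40) {
    q <- sample(3:12, 1)
    n <- sample(1:20, 1)
    Y <- lapply(seq_len(n), function(i)
      sample(q, sample(0:3, 1, prob = c(0.1, 0.5, 0.3, 0.1))))
    Z <- lapply(seq_len(n), function(i) sample(q, sample(0:min(4, q), 1)))
    got <- multilabel_metrics(Y, Z, q)
    expect_equal(unname(unlist(got)), oracle(Y, Z, q), tolerance = 1e-12)
    expect_true(all(unlist(got) >= 0 & unlist(got) <= 1))
  }
})

test_that("top-k exact match requires set equality on both roles", {
  rec <- ranked_df(list(list("R1", "S1"), list(c("R1", "R2"), "S1"),
                        list("R2", "S2")))
  # record matches rank 1 -> hit at every k
  e1 <- entry_with_records("a", list(list("R1", "S1")))
  out <- topk_exact_match(list(rec), list(e1))
  expect_equal(unname(out$hit_rates), rep(1, 4))
  # record matches only rank 3 -> miss at k=1, hit from k=3
  e2 <- entry_with_records("b", list(list("R2", "S2")))
  out2 <- topk_exact_match(list(rec), list(e2))
  expect_equal(unname(out2$hit_rates), c(0, 1, 1, 1))
  # shared solvent but missing reagent is no hit; label order irrelevant
  e3 <- entry_with_records("c", list(list(c("R2", "R1"), "S1")))
  out3 <- topk_exact_match(list(rec), list(e3))
  expect_equal(unname(out3$hit_rates), c(0, 1, 1, 1))  # rank 2 matches as a set
  e4 <- entry_with_records("d", list(list("R3", "S1")))
  expect_equal(unname(topk_exact_match(list(rec), list(e4))$hit_rates),
               rep(0, 4))
})

test_that("rank-window example: a hit only at rank 7 registers at k >= 10", {
  pairs <- lapply(1:12, function(i) list(paste0("R", i), paste0("S", i)))
  rec <- ranked_df(pairs)
  e <- entry_with_records("x", list(list("R7", "S7")))
  out <- topk_exact_match(list(rec), list(e))
  expect_equal(unname(out$hit_rates), c(0, 0, 1, 1))
  # hit rates never decrease with k
  expect_true(all(diff(unname(out$hit_rates)) >= 0))
})

test_that("multi-record table counts minimum hits per bucket", {
  pairs <- lapply(1:25, function(i) list(paste0("R", i), paste0("S", i)))
  rec <- ranked_df(pairs)
  # 2 records, both inside top-20
  e1 <- entry_with_records("a", list(list("R1", "S1"), list("R2", "S2")))
  # 3 records, exactly 1 inside top-20 (R21 is rank 21, R30 absent)
  e2 <- entry_with_records("b", list(list("R3", "S3"), list("R21", "S21"),
                                     list("R30", "S30")))
  # 1 record, no hit
  e3 <- entry_with_records("c", list(list("R99", "S99")))
  out <- multi_record_hits(list(rec, rec, rec), list(e1, e2, e3))
  expect_equal(out$table["2", "1"], 1)
  expect_equal(out$table["2", "2"], 1)
  expect_equal(out$table["3", "1"], 1)
  expect_equal(out$table["3", "2"], 0)
  expect_equal(out$table["3", "3"], 0)
  expect_equal(out$table["1", "1"], 0)
  expect_identical(out$bucket_sizes, c(1L, 1L, 1L, 0L, 0L))
  # within a bucket the j-hit fraction is non-increasing in j
  for (r in 1:3) {
    row <- out$table[r, seq_len(r)]
    expect_true(all(diff(row) <= 0))
  }
})

test_that("temperature metrics and constant baselines are correct", {
  tm <- temperature_metrics(c(20, 20), c(20, 20))
  expect_equal(tm$mae, 0); expect_equal(tm$within_10, 1)
  tm2 <- temperature_metrics(c(10, 30), c(20, 20))
  expect_equal(tm2$mae, 10)
  expect_equal(tm2$within_10, 1); expect_equal(tm2$within_20, 1)
  tm3 <- temperature_metrics(c(0, 0), c(0, 40))
  expect_equal(tm3$baseline_mean_mae, 20)   # mean 20 vs truths {0, 40}
  expect_equal(tm3$baseline_median_mae, 20)
  expect_gte(tm3$within_20, tm3$within_10)
  expect_error(temperature_metrics(1, c(1, 2)), "aligned")
})

test_that("embeddings have layer width, identical rows for identical reactions", {
  d <- small_data()
  m <- small_candidate()
  entries <- d$split$test[c(1, 2, 1)]
  E <- extract_embeddings(m, entries, "shared")
  expect_equal(dim(E), c(3, m$config$hidden))
  expect_identical(E[1, ], E[3, ])
  Er <- extract_embeddings(m, entries, "reagent_task")
  expect_equal(ncol(Er), m$config$task_hidden)
  expect_error(extract_embeddings(m, entries, "bogus"), "arg")
  f <- tempfile(fileext = ".tsv")
  write_embeddings(E, f, tags = c("t1", "t2", "t1"))
  tab <- utils::read.delim(f)
  expect_identical(nrow(tab), 3L)
  expect_equal(ncol(tab), 2 + m$config$hidden)
})

test_that("shared-layer embeddings separate templates (positive silhouette)", {
  d <- small_data()
  m <- small_candidate()
  entries <- d$split$test
  E <- extract_embeddings(m, entries, "shared")
  ids <- vapply(entries, `[[`, character(1), "reaction_id")
  lab <- d$truth$template[ids]
  # mean silhouette over euclidean distances, computed directly
  D <- as.matrix(dist(E))
  sil <- vapply(seq_along(lab), function(i) {
    own <- lab == lab[i]; own[i] <- FALSE
    if (!any(own)) return(NA_real_)
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(lab), lab[i]), function(g)
      mean(D[i, lab == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil, na.rm = TRUE), 0)
})
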