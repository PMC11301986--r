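# Synthetic world generator: determinism, structure, dataset statistics.

test_that("world dimensions echo the configuration and worlds are reproducible", {
  w <- make_world(n_reagents = 50, n_solvents = 20, n_templates = 10,
                  seed = 5)
  expect_length(w$reagents, 50)
  expect_length(w$solvents, 20)
  expect_identical(nrow(w$templates), 10L)
  w2 <- make_world(n_reagents = 50, n_solvents = 20, n_templates = 10,
                   seed = 5)
  expect_identical(w, w2)
  expect_false(identical(w, make_world(50, 20, 10, seed = 6)))
})

test_that("every template has a unique best condition and valid cardinalities", {
  w <- make_world(seed = 17)
  by_t <- split(w$conditions,
                vapply(w$conditions, `[[`, numeric(1), "template"))
  for (conds in by_t) {
    y <- vapply(conds, `[[`, numeric(1), "latent_yield")
    expect_gte(length(conds), 1)
    expect_identical(sum(y == max(y)), 1L)
    for (cd in conds) {
      expect_lte(length(cd$reagents), 3)
      expect_gte(length(cd$reagents), 1)
      expect_lte(length(cd$solvents), 2)
      expect_gte(length(cd$solvents), 1)
      expect_true(cd$latent_yield >= 0 && cd$latent_yield <= 1)
    }
  }
})

test_that("datasets are reproducible and respect record structure", {
  w <- make_world(seed = 23)
  d1 <- sample_dataset(w, 200, seed = 41)
  d2 <- sample_dataset(w, 200, seed = 41)
  expect_identical(d1$entries, d2$entries)
  for (e in d1$entries) {
    expect_gte(length(e$conditions), 1)
    for (cond in e$conditions) {
      expect_true(cond$yield >= 0 && cond$yield <= 1)
      expect_lte(length(cond$reagents), 3)
      expect_lte(length(cond$solvents), 2)
    }
  }
})

test_that("zero noise reproduces latent yields and condition temperatures", {
  w <- make_world(n_templates = 4, seed = 29)
  d <- sample_dataset(w, 60, yield_noise_sd = 0, temp_noise_sd = 0,
                      seed = 43)
  cond_tab <- d$truth$conditions
  for (e in d$entries) {
    t <- d$truth$template[e$reaction_id]
    sub <- cond_tab[cond_tab$template == t, ]
    for (cond in e$conditions) {
      j <- which(sub$reagents == paste(cond$reagents, collapse = ";") &
                   sub$solvents == paste(cond$solvents, collapse = ";"))
      expect_length(j, 1)
      expect_equal(cond$yield, sub$latent_yield[j])
      expect_equal(cond$temperature, sub$temp_mean[j])
    }
  }
})

test_that("multi-record fraction tracks the configured rate", {
  w <- make_world(seed = 7)
  n <- 3000
  d <- sample_dataset(w, n, multi_condition_fraction = 0.088, seed = 11)
  # count on sampled reactions (before rare canonical merges)
  frac <- mean(vapply(d$entries, function(e)
    length(unique(vapply(e$conditions, function(cd)
      rxncond:::context_key(cd$reagents, cd$solvents), character(1)))) > 1,
    logical(1)))
  sd3 <- 3 * sqrt(0.088 * 0.912 / n)
  expect_lt(abs(frac - 0.088), sd3 + 0.01)
})

test_that("label usage is long-tailed: top decile covers most occurrences", {
  w <- make_world(seed = 13)
  d <- sample_dataset(w, 1500, seed = 19)
  freq <- sort(table(unlist(lapply(d$entries, function(e)
    lapply(e$conditions, `[[`, "reagents")))), decreasing = TRUE)
  top_decile <- max(1, ceiling(length(w$reagents) / 10))
  expect_gt(sum(freq[seq_len(min(top_decile, length(freq)))]) / sum(freq),
            0.5)
})

test_that("datasets round-trip through the reader with zero rejections", {
  d <- small_data()
  path <- tempfile(fileext = ".tsv")
  write_dataset(d$entries, path)
  rd <- read_reaction_table(path)
  expect_identical(rd$rejected, 0L)
  expect_length(rd$entries, length(d$entries))
  # canonical reaction SMILES identical after the round trip
  expect_setequal(vapply(rd$entries, `[[`, character(1), "reaction_smiles"),
                  vapply(d$entries, `[[`, character(1), "reaction_smiles"))
})

test_that("dataset files never leak the latent truth", {
  w <- make_world(seed = 3)
  d <- sample_dataset(w, 50, seed = 4)
  path <- tempfile(fileext = ".tsv")
  write_dataset(d$entries, path)
  tab <- utils::read.delim(path)
  expect_identical(names(tab), c("reaction_smiles", "reagents", "solvents",
                                 "temperature_c", "yield"))
  # latent yields (unnoised values) are not reproduced verbatim
  expect_false(any(c("latent_yield", "template", "cond_id") %in% names(tab)))
})

test_that("an external toolkit parses every emitted reaction SMILES", {
  py <- Sys.which("python")
  expect_true(nzchar(py))
  w <- make_world(n_templates = 12, seed = 57)
  d <- sample_dataset(w, 40, seed = 58)
  smis <- vapply(d$entries, `[[`, character(1), "reaction_smiles")
  mols <- unique(unlist(strsplit(unlist(strsplit(smis, ">>", fixed = TRUE)),
                                 ".", fixed = TRUE)))
  script <- sprintf(
    "from rdkit import Chem\nimport sys\nbad=[s for s in %s if Chem.MolFromSmiles(s) is None]\nsys.stdout.write(str(len(bad)))",
    paste0("[", paste(sprintf("'%s'", mols), collapse = ","), "]"))
  f <- tempfile(fileext = ".py"); writeLines(script, f)
  out <- suppressWarnings(system2(py, f, stdout = TRUE, stderr = FALSE))
  expect_identical(tail(out, 1), "0")
})
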