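# Table parsing, label normalization, filtering and the grouped split.

test_that("a minimal valid row becomes one entry with one condition", {
  path <- write_toy_table(list(toy_row(solvents = "CO", yield = 0.9)))
  rd <- read_reaction_table(path)
  expect_length(rd$entries, 1)
  e <- rd$entries[[1]]
  expect_identical(e$reaction_smiles, "CC=O>>CCO")
  expect_length(e$conditions, 1)
  expect_identical(e$conditions[[1]]$solvents, "CO")
  expect_equal(e$conditions[[1]]$yield, 0.9)
  expect_identical(rd$rejected, 0L)
})

test_that("unparsable reaction SMILES are dropped and counted", {
  path <- write_toy_table(list(toy_row(), toy_row("C1CC>>CC")))
  rd <- read_reaction_table(path)
  expect_length(rd$entries, 1)
  expect_identical(rd$rejected, 1L)
})

test_that("rows with one canonical reaction SMILES merge into one entry", {
  path <- write_toy_table(list(
    toy_row("CC=O>>CCO", solvents = "CO", yield = 0.5),
    toy_row("OCC=O>>OCCO", solvents = "O", yield = 0.4),
    toy_row("C(C)=O>>OCC", solvents = "CCO", yield = 0.7)))
  rd <- read_reaction_table(path)
  expect_length(rd$entries, 2)
  merged <- rd$entries[[which(vapply(rd$entries, function(e)
    e$reaction_smiles == "CC=O>>CCO", logical(1)))]]
  expect_length(merged$conditions, 2)
  expect_setequal(vapply(merged$conditions, `[[`, numeric(1), "yield"),
                  c(0.5, 0.7))
})

test_that("percent yields are converted to fractions", {
  path <- write_toy_table(list(toy_row(yield = 97)))
  rd <- read_reaction_table(path)
  expect_equal(rd$entries[[1]]$conditions[[1]]$yield, 0.97)
  expect_identical(rd$log$yield_percent_converted, 1L)
})

test_that("missing required columns are reported by name", {
  df <- data.frame(reaction_smiles = "CC=O>>CCO", reagents = "",
                   solvents = "CO", yield = 0.9)
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_reaction_table(path), "temperature_c")
})

test_that("hydrate names and SMILES merge to one label; roles reassigned by majority", {
  lookup <- read_name_lookup()
  rows <- c(
    replicate(12, toy_row(reagents = "sodium carbonate", solvents = "CO"),
              simplify = FALSE),
    replicate(3, toy_row(reagents = "sodium carbonate monohydrate",
                         solvents = "CO"), simplify = FALSE),
    # methanol (CO) also shows up twice as a reagent; as a solvent 15x above
    replicate(2, toy_row(reagents = "CO", solvents = "O"),
              simplify = FALSE))
  # distinct reaction smiles so entries stay separate
  for (i in seq_along(rows)) {
    rows[[i]]$reaction_smiles <-
      sprintf("%s>>%s", paste0("C", strrep("C", i), "=O"),
              paste0("C", strrep("C", i), "O"))
  }
  rd <- read_reaction_table(write_toy_table(rows))
  nl <- normalize_labels(rd$entries, lookup)
  carb <- canonical_smiles("O=C([O-])[O-].[Na+].[Na+]")
  all_reag <- unlist(lapply(nl$entries, function(e)
    lapply(e$conditions, `[[`, "reagents")))
  all_solv <- unlist(lapply(nl$entries, function(e)
    lapply(e$conditions, `[[`, "solvents")))
  # hydrate and anhydrous names collapsed onto the carbonate SMILES
  expect_identical(sum(all_reag == carb), 15L)
  # methanol is predominantly a solvent: its 2 reagent occurrences moved
  expect_false(canonical_smiles("CO") %in% all_reag)
  expect_identical(unname(nl$roles[canonical_smiles("CO")]), "solvent")
  # unknown names survive verbatim
  rows2 <- list(toy_row(reagents = "proprietary ligand X"))
  nl2 <- normalize_labels(read_reaction_table(write_toy_table(rows2))$entries,
                          lookup)
  expect_true("proprietary ligand X" %in%
                unlist(lapply(nl2$entries[[1]]$conditions, `[[`,
                              "reagents")))
})

test_that("normalize_labels is idempotent", {
  d <- small_data()
  once <- normalize_labels(d$entries)
  twice <- normalize_labels(once$entries)
  expect_identical(once$entries, twice$entries)
})

test_that("filters drop records per rule and respect the frequency fixed point", {
  base <- function(i, reag, solv = "CO", yield = 0.9) {
    r <- toy_row(reagents = reag, solvents = solv, yield = yield)
    r$reaction_smiles <- sprintf("C%s=O>>C%sO", strrep("C", i),
                                 strrep("C", i))
    r
  }
  rows <- list()
  # 12 records with common reagent CC(=O)O; 9 with rare reagent NN
  for (i in 1:12) rows[[length(rows) + 1]] <- base(i, "CC(=O)O")
  for (i in 13:21) rows[[length(rows) + 1]] <- base(i, "NN")
  rows[[length(rows) + 1]] <- base(22, "CC(=O)O", solv = "O;CO;CCO") # 3 solvents
  rows[[length(rows) + 1]] <- base(23, "CC(=O)O", yield = NA)        # no yield
  rd <- read_reaction_table(write_toy_table(rows))
  nl <- normalize_labels(rd$entries)
  fl <- apply_filters(nl$entries, min_label_freq = 10)
  expect_identical(fl$log$cardinality, 1L)
  expect_identical(fl$log$no_solvent_or_yield, 1L)
  expect_identical(fl$log$rare_label, 9L)
  # brute-force recount: every surviving label has frequency >= 10
  freq <- table(unlist(lapply(fl$entries, function(e)
    lapply(e$conditions, function(cd) c(cd$reagents, cd$solvents)))))
  expect_true(all(freq >= 10))
  expect_length(fl$entries, 12)
})

test_that("frequency filtering cascades to a stable fixed point", {
  # NN occurs 3x, always alongside CC(=O)O; CC(=O)O occurs 6x. At threshold
  # 4 the first pass only flags NN, but removing NN's records drags CC(=O)O
  # from 6 to 3, so a second pass must remove the rest too.
  rows <- list()
  mk <- function(i, reag) {
    r <- toy_row(reagents = reag, solvents = "CO")
    r$reaction_smiles <- sprintf("C%s=O>>C%sO", strrep("C", i),
                                 strrep("C", i))
    r
  }
  for (i in 1:3) rows[[length(rows) + 1]] <- mk(i, "NN;CC(=O)O")
  for (i in 4:6) rows[[length(rows) + 1]] <- mk(i, "CC(=O)O")
  for (i in 7:12) rows[[length(rows) + 1]] <- mk(i, "OS(=O)(=O)O")
  rd <- read_reaction_table(write_toy_table(rows))
  nl <- normalize_labels(rd$entries)
  fl4 <- apply_filters(nl$entries, min_label_freq = 4)
  survivors <- unlist(lapply(fl4$entries, function(e)
    lapply(e$conditions, `[[`, "reagents")))
  expect_false(canonical_smiles("CC(=O)O") %in% survivors)
  expect_identical(fl4$log$rare_label, 6L)
  expect_length(fl4$entries, 6)
})

test_that("grouped split is 8:1:1 over entries, deterministic, leak-free", {
  rows <- lapply(1:10, function(i) {
    r <- toy_row()
    r$reaction_smiles <- sprintf("C%s=O>>C%sO", strrep("C", i),
                                 strrep("C", i))
    r
  })
  rd <- read_reaction_table(write_toy_table(rows))
  sp <- grouped_split(rd$entries, seed = 42)
  expect_length(sp$train, 8)
  expect_length(sp$validation, 1)
  expect_length(sp$test, 1)
  sp2 <- grouped_split(rd$entries, seed = 42)
  expect_identical(sp$manifest, sp2$manifest)
  smiles_of <- function(x) vapply(x, `[[`, character(1), "reaction_smiles")
  expect_length(intersect(smiles_of(sp$train),
                          c(smiles_of(sp$validation), smiles_of(sp$test))),
                0)
  expect_error(grouped_split(rd$entries, ratios = c(0.5, 0.2, 0.2)),
               "sum")
})

test_that("multi-record entries stay in one subset", {
  d <- small_data()
  sp <- d$split
  multi <- Filter(function(e) length(e$conditions) > 1, d$entries)
  ids_by_subset <- lapply(sp[c("train", "validation", "test")],
                          function(x) vapply(x, `[[`, character(1),
                                             "reaction_id"))
  for (e in multi) {
    hits <- vapply(ids_by_subset, function(ids) e$reaction_id %in% ids,
                   logical(1))
    expect_identical(sum(hits), 1L)
  }
})

test_that("vocabularies are role-disjoint and serialize bit-stably", {
  d <- small_data()
  v <- d$vocab
  expect_length(intersect(v$reagent$label, v$solvent$label), 0)
  f1 <- tempfile(); f2 <- tempfile()
  write_vocabulary(v, f1)
  write_vocabulary(build_vocabulary(d$entries), f2)
  expect_identical(readLines(f1), readLines(f2))
  v2 <- read_vocabulary(f1)
  expect_identical(v2$reagent$label, v$reagent$label)
  expect_identical(v2$checksum, v$checksum)
})
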