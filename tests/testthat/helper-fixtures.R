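# Shared fixtures, built once per test run and memoised. Everything is
# generated in code; sizes are kept small so the default suite stays fast.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# a small synthetic world + dataset, split and vocabulary
small_data <- function() {
  fixture("small_data", function() {
    world <- make_world(n_reagents = 25, n_solvents = 10, n_templates = 5,
                        seed = 301)
    ds <- sample_dataset(world, 350, seed = 302)
    vocab <- build_vocabulary(ds$entries)
    split <- grouped_split(ds$entries, seed = 303)
    list(world = world, entries = ds$entries, truth = ds$truth,
         vocab = vocab, split = split)
  })
}

# a candidate model trained on the small dataset
small_candidate <- function() {
  fixture("small_candidate", function() {
    d <- small_data()
    cfg <- candidate_config(nbits = 256, hidden = 96, task_hidden = 32,
                            dropout = 0.1, epochs = 15, lr = 2e-3,
                            seed = 311)
    fit_candidate_model(d$split$train, d$vocab, cfg)
  })
}

# a ranking model trained on hard-negative-augmented lists
small_ranking <- function() {
  fixture("small_ranking", function() {
    d <- small_data()
    m <- small_candidate()
    feats <- rxncond:::entry_features(d$split$train, 2, 256)
    lists <- build_training_lists(d$split$train, m, features = feats)
    cfg <- ranking_config(nbits = 256, fp_hidden = 96, cond_hidden = 32,
                          trunk_hidden = 48, epochs = 10, lr = 2e-3,
                          seed = 312)
    fit_ranking_model(lists, d$split$train, d$vocab, cfg, features = feats)
  })
}

# a tiny deterministic world: one condition per template, no noise, so the
# template -> condition mapping is exact
noiseless_data <- function() {
  fixture("noiseless_data", function() {
    world <- make_world(n_reagents = 20, n_solvents = 8, n_templates = 4,
                        seed = 321, n_conditions_range = c(1, 1))
    ds <- sample_dataset(world, 240, multi_condition_fraction = 0,
                         yield_noise_sd = 0, temp_noise_sd = 0, seed = 322)
    vocab <- build_vocabulary(ds$entries)
    split <- grouped_split(ds$entries, seed = 323)
    list(world = world, entries = ds$entries, truth = ds$truth,
         vocab = vocab, split = split)
  })
}

# minimal hand-built reaction entry
toy_entry <- function(id = "T1", yield = 0.9, temperature = 25,
                      reagents = "RG1", solvents = "SV1") {
  list(reaction_id = id, reaction_smiles = "CC=O>>CCO",
       reactants = "CC=O", products = "CCO",
       conditions = list(list(reagents = reagents, solvents = solvents,
                              temperature = temperature, yield = yield)))
}

write_toy_table <- function(rows, path = tempfile(fileext = ".tsv")) {
  df <- do.call(rbind, lapply(rows, as.data.frame,
                              stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

toy_row <- function(reaction_smiles = "CC=O>>CCO", reagents = "",
                    solvents = "CO", temperature_c = 25, yield = 0.9) {
  list(reaction_smiles = reaction_smiles, reagents = reagents,
       solvents = solvents, temperature_c = temperature_c, yield = yield)
}
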