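# Reading, normalization, filtering and splitting of reaction-condition
# tables. An entry is a list(reaction_id, reaction_smiles, reactants,
# products, conditions); each condition is a list(reagents, solvents,
# temperature, yield). Entries sharing one canonical reaction SMILES are
# merged, so an entry may carry several condition records.

REQUIRED_COLS <- c("reaction_smiles", "reagents", "solvents",
                   "temperature_c", "yield")

split_labels <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(character(0))
  v <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  v[nzchar(v)]
}

parse_yield <- function(y) {
  y <- suppressWarnings(as.numeric(y))
  conv <- !is.na(y) & y > 1 & y <= 100
  y[conv] <- y[conv] / 100          # percent input, converted to fraction
  y[!is.na(y) & (y < 0 | y > 1)] <- NA_real_
  list(yield = y, converted = sum(conv))
}

#' Read a reaction-condition table
#'
#' Reads a delimited table (TSV or CSV by extension) with one condition record
#' per row, canonicalizes reaction SMILES, drops unparsable rows, and merges
#' rows with identical canonical reaction SMILES into single entries carrying
#' multiple condition records. An `agents` segment in
#' `reactants>agents>products` SMILES is folded into the reagent labels; a
#' `catalysts` column, if present, likewise. Yields between 1 and 100 are
#' interpreted as percentages and divided by 100.
#'
#' @param path file path; columns `reaction_smiles`, `reagents` (;-separated),
#'   `solvents` (;-separated), `temperature_c`, `yield`.
#' @param name_lookup optional named character vector mapping lowercase
#'   chemical names to SMILES (see [read_name_lookup()]); used later by
#'   [normalize_labels()] and passed through untouched here.
#' @return a list with `entries`, `rejected` (count of unparsable rows),
#'   `log` (per-rule counters), and `name_lookup`.
#' @export
read_reaction_table <- function(path, name_lookup = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  if (nrow(tab) == 0) {
    warning("empty reaction table: ", path)
    return(list(entries = list(), rejected = 0L,
                log = list(), name_lookup = name_lookup))
  }
  missing <- setdiff(REQUIRED_COLS, names(tab))
  if (length(missing)) {
    stop("reaction table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rx <- canonical_reaction(tab$reaction_smiles)
  ok <- !is.na(rx$smiles)
  rejected <- sum(!ok)
  yl <- parse_yield(tab$yield)
  temp <- suppressWarnings(as.numeric(tab$temperature_c))

  entries <- list()
  index <- new.env(parent = emptyenv())
  for (i in which(ok)) {
    reag <- split_labels(tab$reagents[i])
    if ("catalysts" %in% names(tab)) {
      reag <- c(reag, split_labels(tab$catalysts[i]))
    }
    reag <- unique(c(reag, rx$agents[[i]]))
    cond <- list(reagents = reag,
                 solvents = unique(split_labels(tab$solvents[i])),
                 temperature = temp[i],
                 yield = yl$yield[i])
    key <- rx$smiles[i]
    if (exists(key, envir = index, inherits = FALSE)) {
      j <- get(key, envir = index)
      entries[[j]]$conditions <- c(entries[[j]]$conditions, list(cond))
    } else {
      j <- length(entries) + 1L
      assign(key, j, envir = index)
      entries[[j]] <- list(reaction_id = sprintf("R%05d", j),
                           reaction_smiles = key,
                           reactants = rx$reactants[[i]],
                           products = rx$products[[i]],
                           conditions = list(cond))
    }
  }
  list(entries = entries, rejected = rejected,
       log = list(rows = nrow(tab), unparsable = rejected,
                  yield_percent_converted = yl$converted,
                  entries = length(entries)),
       name_lookup = name_lookup)
}

#' Read an offline name-to-SMILES lookup table
#'
#' Two-column TSV (`name`, `smiles`); names are matched case-insensitively.
#' The packaged table (`system.file("extdata", "name_to_smiles.tsv", package =
#' "rxncond")`) covers common reagents and solvents and maps hydrate names to
#' the anhydrous SMILES.
#'
#' @param path path to the TSV.
#' @return named character vector: lowercase name -> SMILES.
#' @export
read_name_lookup <- function(path = system.file("extdata",
                                                "name_to_smiles.tsv",
                                                package = "rxncond")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(tab$smiles, tolower(trimws(tab$name)))
}

# Resolve one raw label to its merged identity: canonical SMILES when the
# label parses as SMILES or resolves through the name lookup; otherwise the
# verbatim text.
resolve_label <- function(labels, name_lookup = NULL) {
  out <- labels
  can <- canonical_smiles(labels)
  hit <- !is.na(can)
  out[hit] <- can[hit]
  if (!is.null(name_lookup) && any(!hit)) {
    idx <- match(tolower(trimws(labels[!hit])), names(name_lookup))
    found <- !is.na(idx)
    if (any(found)) {
      mapped <- canonical_smiles(unname(name_lookup[idx[found]]))
      tmp <- out[!hit]
      tmp[found][!is.na(mapped)] <- mapped[!is.na(mapped)]
      out[!hit] <- tmp
    }
  }
  out
}

#' Merge equivalent labels and reassign chemical roles
#'
#' Labels resolving to the same canonical SMILES (directly or through the
#' name lookup, e.g. a hydrate name and its anhydrous salt) become one label.
#' Every chemical is then assigned exclusively to the role (reagent or
#' solvent) in which it occurs more often dataset-wide; ties go to reagent.
#' The operation is idempotent.
#'
#' @param entries list of reaction entries.
#' @param name_lookup named character vector from [read_name_lookup()].
#' @return list with `entries` (labels rewritten) and `roles` (named character
#'   vector label -> assigned role).
#' @export
normalize_labels <- function(entries, name_lookup = NULL) {
  raw_reag <- unlist(lapply(entries, function(e)
    unlist(lapply(e$conditions, `[[`, "reagents"))))
  raw_solv <- unlist(lapply(entries, function(e)
    unlist(lapply(e$conditions, `[[`, "solvents"))))
  all_raw <- unique(c(raw_reag, raw_solv))
  if (length(all_raw) == 0) {
    return(list(entries = entries, roles = character(0)))
  }
  res_map <- stats::setNames(resolve_label(all_raw, name_lookup), all_raw)
  cnt_r <- table(unname(res_map[raw_reag]))
  cnt_s <- table(unname(res_map[raw_solv]))
  keys <- unique(unname(res_map))
  nr <- as.numeric(cnt_r[keys]); nr[is.na(nr)] <- 0
  ns <- as.numeric(cnt_s[keys]); ns[is.na(ns)] <- 0
  roles <- stats::setNames(ifelse(ns > nr, "solvent", "reagent"), keys)

  entries <- lapply(entries, function(e) {
    e$conditions <- lapply(e$conditions, function(cond) {
      merged <- unique(unname(res_map[c(cond$reagents, cond$solvents)]))
      cond$reagents <- str_sort(merged[roles[merged] == "reagent"])
      cond$solvents <- str_sort(merged[roles[merged] == "solvent"])
      cond
    })
    e
  })
  list(entries = entries, roles = roles)
}

#' Filter condition records
#'
#' Applies, in order: removal of records without a solvent or without a yield;
#' removal of records exceeding the cardinality limits (more than
#' `max_solvents` solvents or `max_reagents` reagents); iterative removal of
#' records containing any label rarer than `min_label_freq`, with frequencies
#' recounted after each pass until a fixed point. Entries left without
#' conditions are dropped.
#'
#' @param entries list of reaction entries with normalized labels.
#' @param max_solvents,max_reagents cardinality limits (defaults 2 and 3).
#' @param min_label_freq minimum dataset-wide label frequency (default 10).
#' @return list with `entries` and `log` (counts removed per rule).
#' @export
apply_filters <- function(entries, max_solvents = 2, max_reagents = 3,
                          min_label_freq = 10) {
  drop_conds <- function(entries, keep_fun) {
    removed <- 0L
    entries <- lapply(entries, function(e) {
      keep <- vapply(e$conditions, keep_fun, logical(1))
      removed <<- removed + sum(!keep)
      e$conditions <- e$conditions[keep]
      e
    })
    list(entries = entries, removed = removed)
  }
  s1 <- drop_conds(entries, function(cond) {
    length(cond$solvents) >= 1 && !is.na(cond$yield)
  })
  s2 <- drop_conds(s1$entries, function(cond) {
    length(cond$solvents) <= max_solvents &&
      length(cond$reagents) <= max_reagents
  })
  entries <- s2$entries
  rare_removed <- 0L
  repeat {
    freq <- table(unlist(lapply(entries, function(e)
      lapply(e$conditions, function(cond) c(cond$reagents, cond$solvents)))))
    rare <- names(freq)[freq < min_label_freq]
    if (length(rare) == 0) break
    st <- drop_conds(entries, function(cond) {
      !any(c(cond$reagents, cond$solvents) %in% rare)
    })
    entries <- st$entries
    rare_removed <- rare_removed + st$removed
    if (st$removed == 0) break
  }
  keep_entry <- vapply(entries, function(e) length(e$conditions) > 0,
                       logical(1))
  list(entries = entries[keep_entry],
       log = list(no_solvent_or_yield = s1$removed,
                  cardinality = s2$removed,
                  rare_label = rare_removed,
                  empty_entries = sum(!keep_entry)))
}

#' Build the reagent and solvent label vocabularies
#'
#' Orders labels by decreasing frequency (ties broken lexicographically) and
#' assigns stable integer indices; the two role vocabularies are disjoint
#' because [normalize_labels()] makes role assignment exclusive.
#'
#' @param entries filtered, normalized entries.
#' @return list with data frames `reagent` and `solvent`
#'   (columns `index`, `label`, `frequency`) and a numeric `checksum`.
#' @export
build_vocabulary <- function(entries) {
  one_role <- function(field) {
    freq <- table(unlist(lapply(entries, function(e)
      lapply(e$conditions, `[[`, field))))
    if (length(freq) == 0) {
      return(data.frame(index = integer(0), label = character(0),
                        frequency = integer(0),
                        stringsAsFactors = FALSE))
    }
    df <- data.frame(label = names(freq), frequency = as.integer(freq),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$frequency, df$label, method = "radix"), ]
    df$index <- seq_len(nrow(df))
    rownames(df) <- NULL
    df[, c("index", "label", "frequency")]
  }
  reagent <- one_role("reagents")
  solvent <- one_role("solvents")
  list(reagent = reagent, solvent = solvent,
       checksum = hash_string(c("r", reagent$label, "s", solvent$label)))
}

#' Write / read a vocabulary file
#'
#' Plain ordered TSV (`index`, `role`, `label`, `frequency`), bit-stable
#' across runs for a fixed dataset.
#' @param vocab result of [build_vocabulary()].
#' @param path file path.
#' @export
write_vocabulary <- function(vocab, path) {
  df <- rbind(cbind(role = "reagent", vocab$reagent),
              cbind(role = "solvent", vocab$solvent))
  df <- df[, c("index", "role", "label", "frequency")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  vocab <- list(
    reagent = df[df$role == "reagent", c("index", "label", "frequency")],
    solvent = df[df$role == "solvent", c("index", "label", "frequency")])
  rownames(vocab$reagent) <- rownames(vocab$solvent) <- NULL
  vocab$checksum <- hash_string(c("r", vocab$reagent$label,
                                  "s", vocab$solvent$label))
  vocab
}

#' Grouped train/validation/test split
#'
#' Splits at the level of reaction entries (each entry already groups all
#' condition records of one canonical reaction SMILES), so no reaction leaks
#' across subsets. Deterministic for a fixed seed.
#'
#' @param entries merged entries.
#' @param ratios three non-negative fractions summing to 1 (default
#'   `c(0.8, 0.1, 0.1)`).
#' @param seed integer seed.
#' @return list with `train`, `validation`, `test` (entry lists), `ratios`,
#'   `seed`, and `manifest` (data frame reaction_id/subset).
#' @export
grouped_split <- function(entries, ratios = c(0.8, 0.1, 0.1), seed = 1) {
  if (length(ratios) != 3 || any(ratios < 0) ||
      abs(sum(ratios) - 1) > 1e-6) {
    stop("ratios must be three non-negative fractions summing to 1",
         call. = FALSE)
  }
  n <- length(entries)
  perm <- with_seed(seed, sample.int(n))
  n_val <- round(n * ratios[2])
  n_test <- round(n * ratios[3])
  n_train <- n - n_val - n_test
  subset <- rep(c("train", "validation", "test"),
                c(n_train, n_val, n_test))
  ids <- vapply(entries, function(e) e$reaction_id, character(1))
  manifest <- data.frame(reaction_id = ids[perm], subset = subset,
                         stringsAsFactors = FALSE)
  list(train = entries[perm[subset == "train"]],
       validation = entries[perm[subset == "validation"]],
       test = entries[perm[subset == "test"]],
       ratios = ratios, seed = seed, manifest = manifest)
}

#' One-call preprocessing pipeline
#'
#' `read_reaction_table` + `normalize_labels` + `apply_filters` +
#' `build_vocabulary` + `grouped_split`.
#'
#' @inheritParams read_reaction_table
#' @inheritParams apply_filters
#' @inheritParams grouped_split
#' @return list with `split`, `vocab`, `entries`, `log`.
#' @export
prepare_dataset <- function(path, name_lookup = NULL,
                            max_solvents = 2, max_reagents = 3,
                            min_label_freq = 10,
                            ratios = c(0.8, 0.1, 0.1), seed = 1) {
  rd <- read_reaction_table(path, name_lookup)
  nl <- normalize_labels(rd$entries, name_lookup)
  fl <- apply_filters(nl$entries, max_solvents, max_reagents, min_label_freq)
  vocab <- build_vocabulary(fl$entries)
  split <- grouped_split(fl$entries, ratios, seed)
  list(split = split, vocab = vocab, entries = fl$entries,
       log = c(rd$log, fl$log))
}
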