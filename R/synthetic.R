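# Synthetic reaction worlds: hermetic datasets with the statistical structure
# the recommender assumes — a fixed library of reaction templates
# (functional-group transforms applied to decorated alkyl/ether scaffolds),
# per-template condition tables with latent yields, long-tailed label usage,
# a small fraction of multi-record reactions, and noisy recorded yields and
# temperatures. A hidden truth table (never written into the dataset files)
# supports benchmarking.

# name = transform; r/p = reactant/product tails appended to a scaffold;
# co = fixed co-reactant molecule (NA = none)
.TEMPLATES <- data.frame(
  name = c("aldehyde_reduction", "esterification", "alkene_hydrogenation",
           "nitrile_reduction", "amination", "amide_coupling",
           "acetylation", "reductive_amination", "cyanation",
           "ketone_reduction", "alcohol_oxidation", "acetamide_formation"),
  r = c("C=O", "C(=O)O", "C=C", "C#N", "Br", "C(=O)Cl",
        "O", "C=O", "I", "C(=O)C", "CO", "N"),
  p = c("CO", "C(=O)OC", "CC", "CN", "N", "C(=O)NC",
        "OC(C)=O", "CNC", "C#N", "C(O)C", "C=O", "NC(C)=O"),
  co = c(NA, "CO", NA, NA, "N", "CN",
         "CC(=O)Cl", "CN", NA, NA, NA, "CC(=O)Cl"),
  stringsAsFactors = FALSE)

# small-molecule libraries for the label vocabularies (reagents and solvents
# kept disjoint so role exclusivity holds by construction)
.REAGENT_LIB <- c(
  "[Na+].[OH-]", "[K+].[OH-]", "O=C([O-])[O-].[Na+].[Na+]",
  "O=C([O-])[O-].[K+].[K+]", "CC(C)(C)[O-].[K+]", "[Li+].[AlH4-]",
  "[Na+].[BH4-]", "[H][H]", "Cl", "OS(=O)(=O)O", "ON(=O)=O", "CC(=O)Cl",
  "CC(=O)OC(C)=O", "ClC(=O)C(=O)Cl", "CCN(CC)CC", "c1ccncc1",
  "CN1CCCC1=O", "CC(C)(C)OC(=O)OC(=O)OC(C)(C)C", "ClCCl",
  "CS(=O)(=O)Cl", "Cc1ccc(cc1)S(=O)(=O)O", "OO", "ClP(Cl)Cl",
  "BrP(Br)Br", "ICl", "[Mg]", "[Zn]", "[Fe]", "[Ni]", "[Pd]",
  "Cl[Pd]Cl", "[Pt]", "CC(=O)[O-].[Na+]", "CC(=O)[O-].[K+]",
  "[Na+].[Cl-]", "[K+].[I-]", "[Na+].[I-]", "BrBr", "ClCl", "II",
  "NN", "CO[Na]", "CC[O-].[Na+]", "OC(=O)C(F)(F)F", "FC(F)(F)S(=O)(=O)O",
  "B(O)O", "CC(C)CB(O)O", "C1CCNCC1", "CN(C)c1ccncc1", "CC(C)N=C=NC(C)C",
  "ClS(=O)Cl", "O=S(Cl)Cl", "CC(C)(C)OO", "CCOC(=O)N=NC(=O)OCC",
  "c1ccc(cc1)P(c1ccccc1)c1ccccc1", "ClCr(=O)(=O)Cl", "O=[Mn]=O",
  "[Na+].[N-]=[N+]=[N-]", "CC1(C)CCCC(C)(C)N1", "CB(O)O")
.SOLVENT_LIB <- c(
  "O", "CO", "CCO", "CC(C)O", "CC(=O)C", "CCOC(C)=O", "C1CCOC1",
  "COCCOC", "CN(C)C=O", "CS(C)=O", "CC#N", "c1ccccc1", "Cc1ccccc1",
  "ClCCCl", "ClC(Cl)Cl", "CCCCCC", "CCCCC", "C1CCCCC1", "COC(C)(C)C",
  "CCOCC", "CN1CCCC1=O", "CC(C)=O", "OCCO", "OCC(O)CO", "CCCO")

#' Build a synthetic reaction world
#'
#' Draws per-template condition tables (reagent/solvent sets with latent mean
#' yields and temperature means) over long-tailed label vocabularies, and
#' fixes the scaffold-decoration machinery that makes reactions of the same
#' template share a learnable fingerprint signal.
#'
#' Within a template, conditions are variations around a core reagent and
#' core solvent (additives swapped in and out), so label marginals are
#' predictable from the reaction fingerprint; the unique best condition has
#' the highest latent yield by construction.
#'
#' @param n_reagents,n_solvents vocabulary sizes (up to the library sizes,
#'   59 and 25).
#' @param n_templates number of reaction templates (up to 12).
#' @param seed integer seed.
#' @param n_conditions_range range of compatible conditions per template.
#' @return an object of class `synthetic_world`.
#' @export
make_world <- function(n_reagents = 40, n_solvents = 15, n_templates = 8,
                       seed = 1, n_conditions_range = c(4, 6)) {
  stopifnot(n_reagents >= 1, n_solvents >= 1, n_templates >= 1,
            n_reagents <= length(.REAGENT_LIB),
            n_solvents <= length(.SOLVENT_LIB),
            n_templates <= nrow(.TEMPLATES))
  reagents <- canonical_smiles(.REAGENT_LIB[seq_len(n_reagents)])
  solvents <- canonical_smiles(.SOLVENT_LIB[seq_len(n_solvents)])
  if (anyNA(reagents) || anyNA(solvents)) {
    stop("vocabulary SMILES failed to parse", call. = FALSE)
  }
  # long-tailed usage weights (Zipf-like)
  w_r <- (seq_len(n_reagents))^-1.8
  w_s <- (seq_len(n_solvents))^-1.3
  temp_grid <- seq(-10, 130, length.out = n_templates)
  with_seed(seed, {
    temp_grid <- sample(temp_grid)
    conditions <- list()
    for (t in seq_len(n_templates)) {
      core_r <- sample(n_reagents, 1, prob = w_r)
      adds <- sample(setdiff(seq_len(n_reagents), core_r), 3, prob =
                       w_r[setdiff(seq_len(n_reagents), core_r)])
      s_pair <- sample(n_solvents, 2, prob = w_s)
      r_sets <- list(core_r, c(core_r, adds[1]), c(core_r, adds[2]),
                     adds[1], c(core_r, adds[3]), adds[2])
      s_sets <- list(s_pair[1], s_pair[1], s_pair[2], s_pair[1],
                     s_pair[2], s_pair[2])
      n_cond <- sample(seq(n_conditions_range[1], n_conditions_range[2]), 1)
      yields <- c(stats::runif(1, 0.80, 0.90),
                  stats::runif(n_cond - 1, 0.30, 0.70))
      t_means <- temp_grid[t] + stats::runif(n_cond, -15, 15)
      for (j in seq_len(n_cond)) {
        conditions[[length(conditions) + 1]] <- list(
          template = t, cond_id = j,
          reagents = str_sort(reagents[r_sets[[j]]]),
          solvents = str_sort(solvents[s_sets[[j]]]),
          latent_yield = yields[j], temp_mean = t_means[j])
      }
    }
  })
  structure(list(reagents = reagents, solvents = solvents,
                 templates = .TEMPLATES[seq_len(n_templates), ],
                 conditions = conditions, seed = seed),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("Synthetic reaction world: %d templates, %d reagent / %d solvent labels, %d compatible conditions\n",
              nrow(x$templates), length(x$reagents), length(x$solvents),
              length(x$conditions)))
  invisible(x)
}

# random alkyl/ether substituent; always starts and ends on carbon, never
# emits an O-O bond, so prefixing any template tail yields valid SMILES.
# 2-9 chain units with optional methyl/ethyl branches span a space of ~1e5
# distinct decorations, enough for tens of thousands of unique scaffolds.
gen_substituent <- function() {
  toks <- "C"
  last <- "C"
  for (k in seq_len(sample(2:8, 1))) {
    unit <- if (last == "O") "C" else
      sample(c("C", "O"), 1, prob = c(0.8, 0.2))
    toks <- c(toks, unit)
    last <- unit
    if (unit == "C" && stats::runif(1) < 0.25) {
      toks <- c(toks, sample(c("(C)", "(CC)"), 1, prob = c(0.8, 0.2)))
    }
  }
  if (last == "O") toks <- c(toks, "C")
  paste(toks, collapse = "")
}

#' Sample a synthetic reaction-condition dataset
#'
#' Each reaction instantiates one template with a fresh scaffold decoration;
#' with probability `multi_condition_fraction` it carries 2-5 condition
#' records, otherwise 1. Records are drawn from the template's compatible
#' conditions with probability increasing in latent yield
#' (weights `exp(yield / 0.2)`); recorded yields are the latent yields plus
#' clamped Gaussian noise, temperatures the condition means plus noise.
#'
#' @param world a `synthetic_world`.
#' @param n_reactions number of reactions.
#' @param multi_condition_fraction fraction of reactions with multiple
#'   records (default 0.088).
#' @param yield_noise_sd,temp_noise_sd Gaussian noise SDs (defaults 0.05 and
#'   5 degrees C).
#' @param seed integer seed.
#' @return list with `entries` (ready for the modelling functions and
#'   round-tripping through [write_dataset()]/[read_reaction_table()]) and
#'   `truth` (hidden table: per-reaction template plus the world's condition
#'   table with latent yields; never written into the dataset files).
#' @export
sample_dataset <- function(world, n_reactions,
                           multi_condition_fraction = 0.088,
                           yield_noise_sd = 0.05, temp_noise_sd = 5,
                           seed = 1) {
  stopifnot(inherits(world, "synthetic_world"), n_reactions >= 1,
            multi_condition_fraction >= 0, multi_condition_fraction <= 1)
  n_templates <- nrow(world$templates)
  cond_by_t <- split(world$conditions,
                     vapply(world$conditions, `[[`, numeric(1), "template"))
  entries <- vector("list", n_reactions)
  truth_template <- integer(n_reactions)
  with_seed(seed, {
    template_of <- sample.int(n_templates, n_reactions, replace = TRUE)
    used <- new.env(parent = emptyenv())
    subs <- character(n_reactions)
    for (i in seq_len(n_reactions)) {
      tries <- 0
      repeat {
        s <- gen_substituent()
        tries <- tries + 1
        # collisions get rarer as the chain grows; extend deterministically
        if (tries > 50) s <- paste0(s, strrep("C", tries - 50))
        key <- paste0(template_of[i], ":", s)
        if (!exists(key, envir = used, inherits = FALSE)) {
          assign(key, TRUE, envir = used)
          subs[i] <- s
          break
        }
      }
    }
    # batch-canonicalize every molecule once (fills the cache)
    tt <- world$templates[template_of, ]
    r_smiles <- paste0(subs, tt$r)
    p_smiles <- paste0(subs, tt$p)
    mols <- unique(c(r_smiles, p_smiles,
                     tt$co[!is.na(tt$co)]))
    can <- canonical_smiles(mols)
    if (anyNA(can)) {
      stop("generated SMILES failed to parse: ",
           paste(mols[is.na(can)], collapse = ", "), call. = FALSE)
    }
    seen <- new.env(parent = emptyenv())
    for (i in seq_len(n_reactions)) {
      conds <- cond_by_t[[as.character(template_of[i])]]
      y <- vapply(conds, `[[`, numeric(1), "latent_yield")
      n_rec <- if (stats::runif(1) < multi_condition_fraction) {
        sample(2:min(5, length(conds)), 1)
      } else 1L
      pick <- sample(seq_along(conds), n_rec, prob = exp(y / 0.2))
      records <- lapply(pick, function(j) {
        list(reagents = conds[[j]]$reagents,
             solvents = conds[[j]]$solvents,
             temperature = conds[[j]]$temp_mean +
               stats::rnorm(1, 0, temp_noise_sd),
             yield = clamp(conds[[j]]$latent_yield +
                             stats::rnorm(1, 0, yield_noise_sd), 0, 1))
      })
      reactants <- canonical_smiles(c(r_smiles[i],
                                      if (!is.na(tt$co[i])) tt$co[i]))
      products <- canonical_smiles(p_smiles[i])
      reactants <- str_sort(reactants)
      rsmi <- paste0(paste(reactants, collapse = "."), ">>",
                     paste(products, collapse = "."))
      if (exists(rsmi, envir = seen, inherits = FALSE)) {
        # two decorations canonicalized to the same molecule: merge records
        j <- get(rsmi, envir = seen)
        entries[[j]]$conditions <- c(entries[[j]]$conditions, records)
        next
      }
      assign(rsmi, i, envir = seen)
      entries[[i]] <- list(
        reaction_id = sprintf("S%05d", i),
        reaction_smiles = rsmi,
        reactants = reactants, products = products,
        conditions = records)
      truth_template[i] <- template_of[i]
    }
  })
  keep <- !vapply(entries, is.null, logical(1))
  entries <- entries[keep]
  truth_template <- truth_template[keep]
  truth_conditions <- do.call(rbind, lapply(world$conditions, function(cd) {
    data.frame(template = cd$template, cond_id = cd$cond_id,
               reagents = paste(cd$reagents, collapse = ";"),
               solvents = paste(cd$solvents, collapse = ";"),
               latent_yield = cd$latent_yield, temp_mean = cd$temp_mean,
               stringsAsFactors = FALSE)
  }))
  list(entries = entries,
       truth = list(template = stats::setNames(
                      truth_template,
                      vapply(entries, `[[`, character(1), "reaction_id")),
                    conditions = truth_conditions))
}

#' Write reaction entries as a condition table
#'
#' One row per condition record, in the format [read_reaction_table()]
#' expects. Holds no latent/truth information.
#'
#' @param entries list of reaction entries.
#' @param path output TSV path.
#' @export
write_dataset <- function(entries, path) {
  rows <- list()
  for (e in entries) {
    for (cond in e$conditions) {
      rows[[length(rows) + 1]] <- data.frame(
        reaction_smiles = e$reaction_smiles,
        reagents = paste(cond$reagents, collapse = ";"),
        solvents = paste(cond$solvents, collapse = ";"),
        temperature_c = cond$temperature,
        yield = cond$yield,
        stringsAsFactors = FALSE)
    }
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
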