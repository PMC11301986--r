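# SMILES canonicalization and molecular graphs via OpenBabel/ChemmineR.
# Results are memoised in a package-local environment: the synthetic worlds
# and real tables reuse a bounded set of distinct molecules, so caching makes
# featurization of large datasets cheap.

.chem_cache <- new.env(parent = emptyenv())

#' Canonicalize SMILES strings
#'
#' Converts SMILES to the toolkit's canonical form. Unparsable inputs map to
#' `NA`. Canonicalization is idempotent: applying it to its own output
#' returns the same string.
#'
#' @param smiles character vector of SMILES (no reaction `>>` arrows).
#' @return character vector of canonical SMILES, `NA` where parsing failed.
#' @export
#' @examples
#' canonical_smiles(c("OCC", "CCO"))  # both "CCO"
canonical_smiles <- function(smiles) {
  out <- rep(NA_character_, length(smiles))
  if (length(smiles) == 0) return(out)
  key <- paste0("can:", smiles)
  cached <- vapply(key, function(k) {
    if (exists(k, envir = .chem_cache, inherits = FALSE)) {
      get(k, envir = .chem_cache)
    } else NA_character_
  }, character(1), USE.NAMES = FALSE)
  todo <- which(is.na(cached) & !is.na(smiles) & nzchar(smiles))
  out[!is.na(cached)] <- cached[!is.na(cached)]
  if (length(todo)) {
    fresh <- canonicalize_raw(smiles[todo])
    out[todo] <- fresh
    for (i in seq_along(todo)) {
      assign(key[todo[i]], fresh[i], envir = .chem_cache)
    }
  }
  out[is.na(smiles) | !nzchar(smiles %||% "")] <- NA_character_
  out
}

# Batch conversion through OpenBabel; OpenBabel aborts a batch at the first
# invalid SMILES, so on a short batch we fall back to per-item conversion.
canonicalize_raw <- function(smiles) {
  conv_many <- function(v) {
    txt <- paste0(paste(v, collapse = "\n"), "\n")
    res <- tryCatch(
      suppressWarnings(suppressMessages(
        ChemmineOB::convertFormat("SMI", "CAN", txt)
      )),
      error = function(e) ""
    )
    lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
    sub("\t.*$", "", lines)
  }
  got <- conv_many(smiles)
  if (length(got) == length(smiles) && all(nzchar(got))) return(got)
  # at least one invalid entry: resolve individually
  vapply(smiles, function(s) {
    g <- conv_many(s)
    if (length(g) == 1 && nzchar(g)) g else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Canonicalize a reaction SMILES
#'
#' Splits `reactants>agents>products` (or `reactants>>products`), canonicalizes
#' each side and returns the canonical `reactants>>products` string together
#' with the per-side molecule lists. Agents, if present, are returned
#' separately so callers can fold them into the reagent labels.
#'
#' @param rxn_smiles character vector of reaction SMILES.
#' @return a list with elements `smiles` (canonical reaction SMILES or `NA`),
#'   `reactants`, `products`, `agents` (lists of character vectors).
#' @export
canonical_reaction <- function(rxn_smiles) {
  n <- length(rxn_smiles)
  res <- list(smiles = rep(NA_character_, n),
              reactants = vector("list", n),
              products = vector("list", n),
              agents = vector("list", n))
  parts <- strsplit(rxn_smiles, ">", fixed = TRUE)
  for (i in seq_len(n)) {
    p <- parts[[i]]
    if (length(p) == 2) p <- c(p[1], "", p[2])
    if (length(p) != 3 || !nzchar(p[1]) || !nzchar(p[3])) next
    rs <- canonical_smiles(strsplit(p[1], ".", fixed = TRUE)[[1]])
    ps <- canonical_smiles(strsplit(p[3], ".", fixed = TRUE)[[1]])
    ag <- if (nzchar(p[2])) {
      canonical_smiles(strsplit(p[2], ".", fixed = TRUE)[[1]])
    } else character(0)
    if (anyNA(rs) || anyNA(ps) || anyNA(ag)) next
    res$reactants[[i]] <- str_sort(rs)
    res$products[[i]] <- str_sort(ps)
    res$agents[[i]] <- str_sort(ag)
    res$smiles[i] <- paste0(paste(res$reactants[[i]], collapse = "."),
                            ">>",
                            paste(res$products[[i]], collapse = "."))
  }
  res
}

# Atomic numbers for the elements the package expects to meet; anything else
# hashes from its symbol, keeping determinism without a full periodic table.
.ATOMIC_NUM <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11, Mg = 12,
                 Al = 13, Si = 14, P = 15, S = 16, Cl = 17, K = 19, Ca = 20,
                 Ti = 22, Cr = 24, Mn = 25, Fe = 26, Ni = 28, Cu = 29,
                 Zn = 30, Br = 35, Pd = 46, Ag = 47, Sn = 50, I = 53,
                 Pt = 78, Li = 3)

#' Parse a molecule into an adjacency-list graph
#'
#' Internal representation used by the fingerprint code: element symbols plus
#' neighbour and bond-order adjacency lists, read from the V2000 MOL block
#' OpenBabel writes for the canonical SMILES. Disconnected SMILES (salts)
#' give one graph with multiple components; single-atom molecules give a
#' graph with no bonds.
#' @noRd
mol_graph <- function(smiles) {
  can <- canonical_smiles(smiles)
  if (is.na(can)) stop("unparsable SMILES: ", smiles, call. = FALSE)
  key <- paste0("graph:", can)
  if (exists(key, envir = .chem_cache, inherits = FALSE)) {
    return(get(key, envir = .chem_cache))
  }
  mol <- suppressWarnings(suppressMessages(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(can, "\n"))))
  lines <- strsplit(mol, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  natom <- as.integer(substr(counts, 1, 3))
  nbond <- as.integer(substr(counts, 4, 6))
  if (is.na(natom) || natom < 1) {
    stop("could not read MOL block for: ", smiles, call. = FALSE)
  }
  atom_lines <- lines[4 + seq_len(natom)]
  elem <- vapply(atom_lines, function(l) {
    strsplit(trimws(substr(l, 31, 34)), " ")[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  nbr <- rep(list(integer(0)), natom)
  bord <- rep(list(numeric(0)), natom)
  bidx <- rep(list(integer(0)), natom)
  if (!is.na(nbond) && nbond > 0) {
    bond_lines <- lines[4 + natom + seq_len(nbond)]
    for (k in seq_len(nbond)) {
      l <- bond_lines[k]
      a <- as.integer(substr(l, 1, 3))
      b <- as.integer(substr(l, 4, 6))
      o <- as.integer(substr(l, 7, 9))
      nbr[[a]] <- c(nbr[[a]], b); bord[[a]] <- c(bord[[a]], o)
      bidx[[a]] <- c(bidx[[a]], k)
      nbr[[b]] <- c(nbr[[b]], a); bord[[b]] <- c(bord[[b]], o)
      bidx[[b]] <- c(bidx[[b]], k)
    }
  }
  g <- list(smiles = can, elem = elem, nbr = nbr, bord = bord, bidx = bidx)
  assign(key, g, envir = .chem_cache)
  g
}

#' Clear the molecule/fingerprint cache
#' @return invisibly, the number of entries removed.
#' @export
clear_chem_cache <- function() {
  n <- length(ls(.chem_cache))
  rm(list = ls(.chem_cache), envir = .chem_cache)
  invisible(n)
}
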