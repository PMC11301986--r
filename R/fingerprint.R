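# Morgan circular count fingerprints and the reaction difference fingerprint.
#
# Atom environments are grown breadth-first from each atom (radius 0..r) and
# hashed with a deterministic integer fold; identifiers fold into a fixed-width
# count vector. Initial atom invariants are (atomic number, degree, bond-order
# sum). An environment is emitted only while its covered bond set still grows,
# so a lone atom contributes exactly one identifier.

morgan_ids <- function(g, radius = 2) {
  natom <- length(g$elem)
  if (natom == 0) return(numeric(0))
  anum <- unname(.ATOMIC_NUM[g$elem])
  anum[is.na(anum)] <- vapply(g$elem[is.na(anum)],
                              function(e) 200 + hash_fold(utf8ToInt(e)) %% 1000,
                              numeric(1))
  deg <- lengths(g$nbr)
  bsum <- vapply(g$bord, function(x) sum(x), numeric(1))
  ids <- vapply(seq_len(natom), function(i) {
    hash_fold(c(anum[i], deg[i], round(bsum[i] * 2)))
  }, numeric(1))
  out <- ids
  covered <- rep(list(integer(0)), natom)
  if (radius >= 1) {
    for (r in seq_len(radius)) {
      new_ids <- ids
      new_cov <- covered
      for (i in seq_len(natom)) {
        if (deg[i] == 0) next
        nb <- g$nbr[[i]]
        pairs <- cbind(g$bord[[i]], ids[nb])
        ord <- order(pairs[, 1], pairs[, 2])
        new_ids[i] <- hash_fold(c(r, ids[i], t(pairs[ord, , drop = FALSE])))
        cov <- covered[[i]]
        for (j in nb) cov <- c(cov, covered[[j]])
        new_cov[[i]] <- unique(c(cov, g$bidx[[i]]))
        if (length(new_cov[[i]]) > length(covered[[i]])) {
          out <- c(out, new_ids[i])
        }
      }
      ids <- new_ids
      covered <- new_cov
    }
  }
  out
}

fold_counts <- function(ids, nbits) {
  v <- numeric(nbits)
  if (length(ids)) {
    tab <- tabulate(as.integer(ids %% nbits) + 1L, nbits)
    v <- as.numeric(tab)
  }
  v
}

#' Morgan count fingerprint of one molecule
#'
#' @param smiles a single SMILES string.
#' @param radius neighbourhood radius (default 2).
#' @param nbits folded length (default 4096).
#' @return numeric count vector of length `nbits`.
#' @export
#' @examples
#' sum(morgan_fingerprint("C") > 0)  # one occupied position for methane
morgan_fingerprint <- function(smiles, radius = 2, nbits = 4096) {
  g <- mol_graph(smiles)
  key <- paste0("fp:", g$smiles, ":", radius, ":", nbits)
  if (exists(key, envir = .chem_cache, inherits = FALSE)) {
    return(get(key, envir = .chem_cache))
  }
  v <- fold_counts(morgan_ids(g, radius), nbits)
  assign(key, v, envir = .chem_cache)
  v
}

#' Summed fingerprint of a molecule set
#'
#' The element-wise sum of the members' count fingerprints, so the vector is
#' linear in the set: `fp({A,B}) = fp(A) + fp(B)`, and invariant to ordering.
#'
#' @param molecules character vector of SMILES.
#' @inheritParams morgan_fingerprint
#' @return numeric count vector of length `nbits`.
#' @export
molecule_set_fingerprint <- function(molecules, radius = 2, nbits = 4096) {
  v <- numeric(nbits)
  for (m in molecules) v <- v + morgan_fingerprint(m, radius, nbits)
  v
}

#' Reaction difference fingerprint
#'
#' Concatenates the product-set fingerprint with the signed difference
#' (reactants minus products), yielding a vector of length `2 * nbits`. The
#' difference half carries the transformation; because the per-molecule
#' fingerprints are counts, it also carries stoichiometry.
#'
#' @param reactants,products character vectors of SMILES.
#' @inheritParams morgan_fingerprint
#' @return numeric vector of length `2 * nbits`.
#' @export
reaction_fingerprint <- function(reactants, products, radius = 2,
                                 nbits = 4096) {
  if (length(reactants) < 1 || length(products) < 1) {
    stop("a reaction needs at least one reactant and one product",
         call. = FALSE)
  }
  fp_r <- molecule_set_fingerprint(reactants, radius, nbits)
  fp_p <- molecule_set_fingerprint(products, radius, nbits)
  c(fp_p, fp_r - fp_p)
}

# Feature matrix for a list of reaction entries (rows = entries).
entry_features <- function(entries, radius = 2, nbits = 4096) {
  n <- length(entries)
  X <- matrix(0, n, 2 * nbits)
  for (i in seq_len(n)) {
    X[i, ] <- reaction_fingerprint(entries[[i]]$reactants,
                                   entries[[i]]$products, radius, nbits)
  }
  rownames(X) <- vapply(entries, function(e) e$reaction_id, character(1))
  X
}
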