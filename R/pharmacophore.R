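# Compact pharmacophore perception over parsed atom/bond tables.
#
# Families follow the conventional feature-factory vocabulary (Donor,
# Acceptor, Aromatic, NegIonizable, PosIonizable, Hydrophobe); the
# perception rules are deliberately small graph rules adequate for neutral
# drug-like molecules, not a full aromaticity/protonation model.

# Smallest ring through each bond, via igraph shortest paths with the bond
# removed. Returns a list of unique atom-index vectors (sizes 3..7).
find_rings <- function(mol) {
  bonds <- mol$bonds
  if (nrow(bonds) < 3L) return(list())
  g <- igraph::graph_from_data_frame(
    data.frame(from = bonds$a1, to = bonds$a2),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(mol$atoms))))
  rings <- list()
  for (i in seq_len(nrow(bonds))) {
    g2 <- igraph::delete_edges(g, i)
    sp <- suppressWarnings(igraph::shortest_paths(
      g2, from = as.character(bonds$a1[i]), to = as.character(bonds$a2[i])))
    path <- sp$vpath[[1L]]
    if (length(path) >= 3L && length(path) <= 7L) {
      ring <- sort(as.integer(names(path)))
      key <- paste(ring, collapse = ",")
      rings[[key]] <- ring
    }
  }
  unname(rings)
}

ring_is_aromatic <- function(ring, mol) {
  els <- mol$atoms$element[ring]
  b <- mol$bonds
  inring <- b$a1 %in% ring & b$a2 %in% ring
  n_double <- sum(b$order[inring] == 2L)
  if (length(ring) == 6L) all(els %in% c("C", "N")) && n_double == 3L
  else if (length(ring) == 5L) all(els %in% c("C", "N", "O", "S")) &&
    n_double == 2L
  else FALSE
}

neighbours_of <- function(mol, i) {
  b <- mol$bonds
  c(b$a2[b$a1 == i], b$a1[b$a2 == i])
}

# Is atom i a carbonyl carbon (C with a double bond to O)?
is_carbonyl_c <- function(mol, i) {
  if (mol$atoms$element[i] != "C") return(FALSE)
  b <- mol$bonds
  any((b$a1 == i & b$order == 2L & mol$atoms$element[b$a2] == "O") |
        (b$a2 == i & b$order == 2L & mol$atoms$element[b$a1] == "O"))
}

#' Perceive pharmacophore features of a molecule
#'
#' Assigns feature-family annotations to atom groups: hydrogen-bond donors
#' (N/O bearing H), acceptors (O; N outside amides and aromatic N-H),
#' aromatic rings (5/6-membered with the alternating bond pattern),
#' acidic groups (carboxylic acids), basic groups (non-amide sp3 amines)
#' and chain hydrophobes (carbons with only carbon neighbours).
#'
#' @param smiles SMILES string.
#' @return A data.frame with columns `family`, `type`, `atoms` (1-based
#'   comma-separated atom tuple), ordered by (first atom index, family);
#'   zero rows when no feature is perceived.
#' @export
perceive_features <- function(smiles) {
  mol <- parse_smiles(smiles)
  at <- mol$atoms
  rings <- find_rings(mol)
  arom <- Filter(function(r) ring_is_aromatic(r, mol), rings)
  aromatic_atoms <- unique(unlist(arom))
  feats <- list()
  add <- function(family, type, atoms) {
    feats[[length(feats) + 1L]] <<- list(family = family, type = type,
                                         atoms = sort(as.integer(atoms)))
  }
  for (r in arom)
    add("Aromatic", paste0("Arom", length(r)), r)
  for (i in seq_len(nrow(at))) {
    el <- at$element[i]
    nb <- neighbours_of(mol, i)
    if (el %in% c("N", "O") && at$n_h[i] >= 1)
      add("Donor", "SingleAtomDonor", i)
    if (el == "O")
      add("Acceptor", "SingleAtomAcceptor", i)
    if (el == "N") {
      amide <- any(vapply(nb, function(j) is_carbonyl_c(mol, j), logical(1)))
      aromatic_nh <- (i %in% aromatic_atoms) && at$n_h[i] >= 1
      if (!amide && !aromatic_nh)
        add("Acceptor", "SingleAtomAcceptor", i)
      b <- mol$bonds
      all_single <- all(b$order[b$a1 == i | b$a2 == i] == 1L)
      if (!amide && all_single && !(i %in% aromatic_atoms))
        add("PosIonizable", "BasicGroup", i)
    }
    if (el == "C" && is_carbonyl_c(mol, i)) {
      b <- mol$bonds
      o_dbl <- nb[at$element[nb] == "O" &
                    vapply(nb, function(j) any((b$a1 == i & b$a2 == j |
                                                  b$a2 == i & b$a1 == j) &
                                                 b$order == 2L), logical(1))]
      o_oh <- nb[at$element[nb] == "O" & at$n_h[nb] >= 1]
      if (length(o_dbl) >= 1L && length(o_oh) >= 1L)
        add("NegIonizable", "AcidicGroup", c(i, o_dbl[1L], o_oh[1L]))
    }
    if (el == "C" && !(i %in% aromatic_atoms) && length(nb) >= 1L &&
        all(at$element[nb] == "C"))
      add("Hydrophobe", "ChainHydrophobe", i)
  }
  if (length(feats) == 0L)
    return(data.frame(family = character(), type = character(),
                      atoms = character(), stringsAsFactors = FALSE))
  df <- data.frame(
    family = vapply(feats, `[[`, "", "family"),
    type = vapply(feats, `[[`, "", "type"),
    atoms = vapply(feats, function(f) paste(f$atoms, collapse = ","), ""),
    first_atom = vapply(feats, function(f) f$atoms[[1L]], 0L),
    stringsAsFactors = FALSE)
  df <- df[order(df$first_atom, df$family), c("family", "type", "atoms")]
  rownames(df) <- NULL
  df
}

#' Chemical-text words of a drug
#'
#' Serialises the perceived pharmacophore features as the drug's "chemical
#' text": for each feature, three consecutive words -- the family name,
#' the type name, and the atom tuple rendered as `"(i,j,...)"` (1-based,
#' no spaces) -- ordered by (first atom index, family name). Deterministic
#' for a given SMILES; may be empty for featureless molecules.
#'
#' @param smiles SMILES string.
#' @return Character vector of words.
#' @export
chemical_text <- function(smiles) {
  f <- perceive_features(smiles)
  if (nrow(f) == 0L) return(character())
  as.vector(t(cbind(f$family, f$type, paste0("(", f$atoms, ")"))))
}

#' Raw SMILES characters as text words
#'
#' The text stream of the image+SMILES ablation: each character of the
#' SMILES string becomes one word.
#'
#' @param smiles SMILES string.
#' @return Character vector of single-character words.
#' @export
smiles_text <- function(smiles) {
  strsplit(smiles, "")[[1L]]
}
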