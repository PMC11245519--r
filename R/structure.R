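# Ligand-contact extraction from a protein-ligand structure: the
# evidence layer from which the binding motif is derived.  All rules are
# heavy-atom only; hydrogens are ignored throughout.

RING_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"))

AROMATIC_RES <- names(RING_ATOMS)

heavy <- function(atoms) atoms[!atoms$element %in% c("H", "D"), , drop = FALSE]

select_ligand <- function(structure, hetResidue, chain = NULL) {
  lig <- structure[structure$het & structure$residue_name == hetResidue, ,
                   drop = FALSE]
  if (!is.null(chain)) lig <- lig[lig$chain_id == chain, , drop = FALSE]
  lig <- heavy(lig)
  if (nrow(lig) == 0L)
    stop("ligand '", hetResidue, "' selects no heavy atoms")
  lig
}

pair_dists <- function(a, b) {
  # |a| x |b| Euclidean distance matrix
  am <- as.matrix(a[c("x", "y", "z")])
  bm <- as.matrix(b[c("x", "y", "z")])
  d2 <- outer(rowSums(am^2), rowSums(bm^2), "+") - 2 * tcrossprod(am, bm)
  sqrt(pmax(d2, 0))
}

#' Find ligand-contacting residues
#'
#' Reports every protein residue with a heavy atom within `cutoff` of a
#' heavy ligand atom, with the minimal heavy-atom pair distance per
#' residue.  The contract is the exhaustive all-pairs result.
#'
#' @param structure Atom table from [readStructure()].
#' @param hetResidue 3-letter het residue name of the ligand (e.g.
#'   `"URC"` for uric acid).
#' @param chain Optional chain restriction for the ligand.
#' @param cutoff Contact distance cutoff in Angstrom (default 3.5).
#' @return A data.frame sorted by `residue_seq` with columns
#'   `residue_name`, `residue_seq`, `chain_id`, `min_distance`, `label`
#'   (filled by [labelContacts()], `NA` here).
#' @export
findLigandContacts <- function(structure, hetResidue, chain = NULL,
                               cutoff = 3.5) {
  if (cutoff <= 0) stop("cutoff must be positive")
  prot <- heavy(structure[!structure$het, , drop = FALSE])
  if (nrow(prot) == 0L) stop("structure contains no protein atoms")
  lig <- select_ligand(structure, hetResidue, chain)
  d <- pair_dists(prot, lig)
  mind <- apply(d, 1L, min)
  hit <- mind <= cutoff
  if (!any(hit))
    return(data.frame(residue_name = character(), residue_seq = integer(),
                      chain_id = character(), min_distance = numeric(),
                      label = character()))
  key <- paste(prot$chain_id, prot$residue_seq)[hit]
  byres <- split(mind[hit], key)
  first <- match(names(byres), key)
  out <- data.frame(
    residue_name = prot$residue_name[hit][first],
    residue_seq = prot$residue_seq[hit][first],
    chain_id = prot$chain_id[hit][first],
    min_distance = vapply(byres, min, numeric(1)),
    label = NA_character_, stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$residue_seq), , drop = FALSE]
}

#' Label contacts with light-weight interaction categories
#'
#' `hydrogen-bond-capable`: the minimal-distance atom pair of the
#' residue is N/O against N/O at 3.5 Angstrom or less.
#' `aromatic-proximal`: the residue is F/Y/W/H and a side-chain ring
#' atom lies within `cutoff + 1` Angstrom of a ligand ring (C or N)
#' atom -- a bookkeeping label for candidate stacking partners; ring
#' plane geometry is deliberately not verified.  Everything else is
#' `other`.
#'
#' @param contacts Output of [findLigandContacts()].
#' @param structure The atom table the contacts came from.
#' @param hetResidue,chain Ligand selector as in [findLigandContacts()].
#' @param cutoff The contact cutoff used (default 3.5).
#' @return `contacts` with the `label` column filled.
#' @export
labelContacts <- function(contacts, structure, hetResidue, chain = NULL,
                          cutoff = 3.5) {
  if (nrow(contacts) == 0L) return(contacts)
  lig <- select_ligand(structure, hetResidue, chain)
  ligRing <- lig[lig$element %in% c("C", "N"), , drop = FALSE]
  prot <- heavy(structure[!structure$het, , drop = FALSE])
  labs <- character(nrow(contacts))
  for (i in seq_len(nrow(contacts))) {
    resAtoms <- prot[prot$residue_seq == contacts$residue_seq[i] &
                     prot$chain_id == contacts$chain_id[i], , drop = FALSE]
    d <- pair_dists(resAtoms, lig)
    hb <- FALSE
    if (min(d) <= 3.5) {
      pair <- which(d == min(d), arr.ind = TRUE)[1L, ]
      hb <- resAtoms$element[pair[1L]] %in% c("N", "O") &&
        lig$element[pair[2L]] %in% c("N", "O")
    }
    arom <- FALSE
    if (contacts$residue_name[i] %in% AROMATIC_RES && nrow(ligRing)) {
      ring <- resAtoms[resAtoms$atom_name %in%
                         RING_ATOMS[[contacts$residue_name[i]]], ,
                       drop = FALSE]
      if (nrow(ring))
        arom <- min(pair_dists(ring, ligRing)) <= cutoff + 1.0
    }
    labs[i] <- if (hb) "hydrogen-bond-capable"
               else if (arom) "aromatic-proximal" else "other"
  }
  contacts$label <- labs
  contacts
}

#' Candidate binding positions from a contact table
#'
#' @param contacts Output of [findLigandContacts()].
#' @return Ascending, de-duplicated residue indices (empty input gives an
#'   empty vector).
#' @export
proposeBindingPositions <- function(contacts) {
  sort(unique(as.integer(contacts$residue_seq)))
}
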